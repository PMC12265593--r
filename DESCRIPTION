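Package: stweave
Title: Multi-Scale Multimodal Representation Learning and Conditional
    Generation for Image-Based Spatial Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds matched cell-, niche- and tissue-level image/expression
    datasets from segmented image-based spatial transcriptomics slides
    (maximum-intensity projection, 8-bit normalization, minimal-square cell
    crops, 256-px niche and 1024-px tissue tiling with exact gene-mass
    pooling), and learns unified single-cell embeddings by cross-attention
    fusion of vision-transformer image tokens with expression-modulated gene
    tokens, aggregated hierarchically across niche and tissue scales.
    Training is self-supervised via dual decoders (pixel reconstruction and
    masked-gene regression). A conditional latent-diffusion decoder
    synthesizes cell images from the unified embedding under classifier-free
    guidance, with importance-guided non-exclusive token merging to
    accelerate sampling. Includes a synthetic slide generator with known
    morphology/expression coupling for end-to-end verification, evaluation
    harnesses (PSNR, SSIM, cross-modal correlation, clustering and
    classification heads), and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tiff,
    png,
    jsonlite,
    yaml,
    mclust
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
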