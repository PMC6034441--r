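Package: fieldvision
Title: 2D and 3D Machine Vision for Plants and Crops in the Field
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Photometric-stereo surface recovery (per-pixel normals and
    albedo from multi-light image stacks under the Lambertian model,
    including a two-source moving-platform variant and least-squares
    gradient-field integration), curvature analysis of the recovered
    surfaces (HK segmentation, shape index, meristem localisation, 3D
    leaf area), texture-entropy segmentation of broad-leaved weeds in
    grass, a depth-camera potato metrology pipeline (belt normalisation,
    ellipsoid fitting with watershed splitting of touching tubers,
    virtual sieving and size banding), and GPS geo-binned yield heat
    maps. A synthetic-scene generator renders every input with known
    ground truth so all pipelines are testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    tiff,
    yaml,
    grDevices,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
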