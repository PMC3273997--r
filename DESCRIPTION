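Package: canopy3d
Title: Canopy Structure Extraction from Multi-Station Terrestrial Lidar Point Clouds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs crop-canopy structure from high-resolution terrestrial
    lidar scans taken from several stations around the canopy. Provides
    point-to-point iterative closest point (ICP) co-registration of per-station
    point clouds, triangulation of individually labeled leaves into surface
    meshes, and extraction of per-leaf areas, vertical leaf area density (LAD)
    profiles, leaf area index (LAI), and leaf inclination angles from mesh
    normals. A virtual scanner simulates multi-station scans of parametric
    curved-leaf canopies with occlusion and range noise, supplying fully
    ground-truthed data for validation. Includes readers and writers for ASCII
    PLY, XYZ and CSV point clouds and PLY/OBJ meshes, plus a command-line
    interface chaining simulate, register, mesh and traits stages.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    RANN,
    data.table,
    jsonlite,
    yaml,
    optparse,
    withr,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deldir
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
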