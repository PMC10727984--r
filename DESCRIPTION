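Package: agrishock
Title: Counterfactual Agricultural Input-Shock Analysis on Gridded Cropland
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stratifies gridded cropland into climate bins defined by joint
    quintiles of growing degree days and annual precipitation, fits per-bin
    random-forest yield models with spatially blocked train/test splits
    repeated over iterations, predicts crop yields under counterfactual
    reductions of off-farm inputs (N, P, K fertilizer, machinery, pesticides),
    and aggregates yield changes to cell, country and global production
    changes. Includes a synthetic gridded-world generator with a known
    saturating yield response so that counterfactual predictions can be
    checked against ground truth, plus Nash-Sutcliffe model evaluation and
    iteration-based uncertainty measures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ranger,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    randomForest,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
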