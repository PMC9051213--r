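Package: dendrilearn
Title: Dendritic Learning: Tree Backpropagation, Input Crosses and
    Least-Action Perceptron Committees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Training algorithms for biologically-motivated dendritic
    learning on feedforward tree networks: exact backpropagation through
    sigmoid layers with an accumulative-average-field subtraction on the
    first hidden layer, momentum updates with multiplicative weight decay,
    order-3 input-cross feature expansion with micro-canonical per-unit
    assignment, the dendritic-amplification cross algebra, and per-digit
    Hebbian committees of sign perceptrons trained by the least-action
    rule. Includes IDX (MNIST-dialect) readers and writers, per-example
    input normalization with zero-variance masking, soft-committee
    ensemble evaluation, power-law learning-curve fits, and a synthetic
    image-fixture generator so every algorithm is exercisable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    ggplot2,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
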