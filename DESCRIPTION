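Package: trackinfo
Title: Feedback and Feedforward Information Rates in Visuomotor Tracking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes the information shared between a moving target and a
    tracking response into a real-time feedback component (transfer-entropy
    style, delayed by the visuomotor delay) and a predictive feedforward
    component. Mutual and conditional mutual information are estimated with
    the Gaussian copula method with analytic (Wishart digamma) bias
    correction of sample log-determinants. The visuomotor delay is estimated
    as the peak latency of the transfer-entropy curve. A delay-augmented
    linear-quadratic-Gaussian simulator of the tracking task (Kalman filter
    plus receding-horizon quadratic control) provides model-internal
    ground-truth information rates against which the estimators are
    validated, together with an AR(2) resonator target-signal generator with
    controllable predictability.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
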