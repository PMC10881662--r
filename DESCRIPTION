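Package: dyadgrid
Title: Grid Sequence Analysis of Dyadic Punishment Trajectories in the
    Interactive Taylor Aggression Paradigm
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and analyses trial-by-trial monetary punishment
    selections of dyads playing the interactive Taylor Aggression Paradigm
    (iTAP). Encodes joint trajectories on a 10x10 state-space grid,
    computes optimal-matching edit distances under a Manhattan cost model,
    and clusters dyads with Ward linkage to recover aggression subtypes.
    Includes the derived aggression scores (block means, dyad mean and
    difference scores, zero-aggression counts, pre-post differences,
    outcome-conditioned means), questionnaire subscale scoring with
    Cronbach's alpha, a reciprocity-based synthetic cohort generator, and
    the manipulation-check statistics: generalized estimating equations
    with exchangeable working correlation and robust covariance,
    Kruskal-Wallis and Dunn post-hoc tests, Spearman correlations and
    chi-square tests with Bonferroni multiplicity control.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    mclust,
    sandwich,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
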