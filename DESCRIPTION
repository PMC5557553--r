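Package: lingnet
Title: Language Games and the Formation of Linguistic Categories on Social Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based simulation of grounded linguistic categorization on
    social networks. Agents equipped with Gaussian reactive-unit category
    networks and associative lexicons play discrimination, guessing and naming
    games over configurable interaction graphs (complete, star with biased
    speaker/hearer roles, and degree-regular graphs optimized for centrality
    objectives by simulated annealing). The package generates color-chip
    environments in CIE LAB space with family-resemblance frequency structure,
    runs multi-phase experiments in which the network topology or the stimulus
    environment changes mid-run, measures network-specific and global
    communicative success with frozen probe games, and reproduces the
    statistical comparisons (one-way ANOVA, Bartlett, Tukey HSD, paired t)
    used to analyze them.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
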