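Package: coordnorm
Title: Coordinated Multi-Agent Q-Learning for Norm Emergence Under
    Limited Communication
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based simulation of social norm emergence in populations
    of cooperating agents connected by a network, in the spirit of
    coordination among cells in biological systems. Agents play pairwise
    coordination games on the edges of a coordination graph and learn
    edge-factored Q-values cooperatively. Joint actions are selected with
    the max-plus (max-sum) message-passing algorithm, and each agent can
    dynamically shrink the set of neighbours it exchanges messages with
    (randomly, with decay, or by bounding the potential utility loss of
    dropped neighbours) to trade learning performance against
    communication cost. Includes independent Q-learning and distributed
    value function baselines, generators for regular, random, small-world
    and scale-free networks, an exhaustive joint-action oracle for
    testing, experiment configuration, metrics collection and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
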