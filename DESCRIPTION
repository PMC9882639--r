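Package: sensefactor
Title: Psychometric Integrative Data Analysis of Sensory Reactivity Questionnaires
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for pooled psychometric analysis of caregiver-reported sensory
    reactivity items (hyperreactivity, hyporeactivity, sensory seeking) across
    studies and questionnaire versions. Provides an item-bank data model with
    instrument crosswalks and reverse-scoring, polychoric correlation estimation
    under planned missingness, unidimensional and bifactor graded response models
    estimated by marginal maximum likelihood EM with bifactor dimension reduction,
    ICLUST-based iterative scale refinement, exploratory graph analysis with
    EBIC-selected graphical lasso networks and Walktrap communities, bifactor
    reliability and explained-common-variance indices with construct
    interpretability decision rules, Bayesian random-effects integrative data
    analysis of demographic and clinical correlates with ROPE Bayes factors and
    heterogeneity summaries, and a synthetic multi-study data generator for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    tools,
    utils,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mvtnorm,
    rjags,
    coda
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'bifactor.R'
    'bifactorIndices.R'
    'cfa.R'
    'ega.R'
    'grm.R'
    'iclust.R'
    'ida.R'
    'itemBank.R'
    'pipeline.R'
    'polychoric.R'
    'refine.R'
    'simulate.R'
    'utils.R'
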