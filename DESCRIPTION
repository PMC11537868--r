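Package: abmlm
Title: Region-Aware Masked Language Modelling for Antibody Variable Domains
Version: 0.1.0
Authors@R: person("Repo", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for training and evaluating small masked-language models of
    antibody Fv (variable-fragment) amino-acid sequences. Implements a
    region-aware masking curriculum that corrupts a high fraction of CDR-H3
    plus span masking elsewhere, a transformer encoder with disentangled
    relative-position attention, identity-based corpus curation (two-stage
    greedy clustering at 80 percent / 50 percent identity), region-restoration
    and truncation-robustness evaluation protocols, and two frozen-encoder
    downstream heads (contrastive heavy-light chain pairing and CDR-H3
    binding classification). Ships a synthetic antibody grammar that generates
    annotated Fv corpora with planted pairing and binding rules for
    desk-scale, fully reproducible experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
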