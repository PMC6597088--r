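Package: indelscan
Title: Consensus Indel Detection, Consequence Annotation and Mixed-Model
    Association in Experimental Pig Crosses
Version: 0.1.0
Authors@R:
    person("IBCross", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline from multi-caller indel call-sets to trait
    association. Provides left-alignment normalization of indel
    representations, a three-caller consensus engine with exact filter
    accounting (genotype concordance, multi-allelic and fixed-alternative
    filters), a minimal variant-consequence annotator with severity
    classification and protein-level change reporting, founder-frequency
    candidate selection, and a linear mixed model association scan with a
    centred genomic relatedness matrix and Benjamini-Hochberg false
    discovery rate control. A seeded synthetic-data module emulates the
    full experimental design (two Iberian boars and five Landrace sows as
    founders, three noisy caller call-sets, three BC1 backcross
    populations, fatty-acid-like phenotypes) so every stage is testable
    end-to-end without the original sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
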