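Package: opamcdm
Title: Ordinal Priority Approach for Group Multi-Attribute Decision Making
Version: 1.0.0
Author: Package Author
Maintainer: Package Author <author@example.org>
Description: Implements the Ordinal Priority Approach (OPA) for group
    multiple-attribute decision making: purely ordinal preferences of a
    ranked expert panel over ranked attributes and, within each attribute,
    ranked alternatives are turned into cardinal weights by maximizing the
    minimum scaled adjacent-rank weight gap subject to normalization
    (a max-min linear program). Provides a fitting function returning a
    classed model object with print, summary, coef and plot methods; an
    exact closed-form solution path for complete strict instances that
    cross-checks the LP; lexicographic expert prioritization from ordinal
    profile scales; leave-one-expert-out sensitivity analysis; a synthetic
    instance generator based on the Mallows (Kendall-distance exponential)
    ranking model; CSV and JSON readers and writers; and the nine-expert,
    six-attribute, four-alternative at-home rehabilitation case study as a
    built-in fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: boot, jsonlite, graphics, stats, utils
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
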