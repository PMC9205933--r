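Package: rvopathways
Title: Treatment Pathways and Injection Intensity for Macular Edema after
    Retinal Vein Occlusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives lines of therapy, treatment pathways and injection
    intensity statistics for intravitreal treatment of macular edema secondary
    to retinal vein occlusion, from minimal OMOP-CDM-shaped event tables
    (person, drug exposure, condition occurrence, observation period).
    Implements cohort phenotyping with an index date, a 180-day diagnosis
    inclusion window and exclusion concept sets; the line-of-therapy collapse
    rule under which re-prescription of an earlier drug does not open a new
    line; hierarchical pathway trees with sunburst and Sankey data exports;
    per-era, per-first-drug-class injection intensity tables with configurable
    denominators; aggregate-only multi-site merging; and a synthetic
    electronic-health-record generator with closed-form expected summaries for
    end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
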