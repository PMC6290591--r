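Package: simaudit
Title: Contextual Lexical Auditing of SNOMED CT Similarity Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Audits the structural modeling of SNOMED CT concepts in the
    context of their lexical neighbours. Reads RF2 snapshot releases, groups
    concepts whose descriptions differ by exactly one word after stop-word
    removal into similarity sets, compares parent, attribute and role-group
    counts across each set, and flags sets with modeling discrepancies for
    manual audit. Includes a synthetic RF2 release generator with a planted
    ground-truth manifest so the full pipeline is testable without a SNOMED
    CT license.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
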