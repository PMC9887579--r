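# Builds inst/extdata/ukb_showcase_field_map_synthetic.tsv.
# SYNTHETIC STAND-IN: the official biobank showcase field assignment for
# the 249 released biomarkers is not bundled here; this file assigns
# sequential field IDs (23400 + catalog index) to the released tiers in
# catalog order so the showcase-dialect reader can be exercised and the
# lookup replaced wholesale by the real mapping.
library(readr)
catalog <- read_tsv(file.path("inst", "extdata", "biomarker_catalog.tsv"),
                    show_col_types = FALSE)
released <- catalog[catalog$tier %in% c("non_derived", "composite", "ratio"), ]
map <- data.frame(field_id = as.character(seq(23400, length.out = nrow(released))),
                  name = released$name)
write_tsv(map, file.path("inst", "extdata",
                         "ukb_showcase_field_map_synthetic.tsv"))
cat("wrote", nrow(map), "field mappings\n")
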