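test_that("catalog tier counts match the biomarker panel structure", {
  counts <- glance(the_catalog)
  expect_equal(counts$n_non_derived, 107)
  expect_equal(counts$n_composite, 61)
  expect_equal(counts$n_ratio, 81)
  expect_equal(counts$n_extended_ratio, 76)
  expect_equal(counts$n_definitions, 325)
})

test_that("dependency graph is acyclic and bottoms out at non-derived names", {
  topo <- attr(the_catalog, "topo_order")
  expect_setequal(topo, the_catalog$name)
  # every formula operand appears earlier in the topological order
  pos <- setNames(seq_along(topo), topo)
  formulas <- attr(the_catalog, "formulas")
  for (nm in the_catalog$name[the_catalog$tier != "non_derived"]) {
    expect_true(all(pos[formulas[[nm]]$args] < pos[nm]))
  }
})

test_that("malformed catalogs fail validation with every violation listed", {
  bad <- the_catalog
  bad$formula[bad$name == "PUFA"] <- "Omega_3 + NotABiomarker"
  tf <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(as_tibble(bad), tf)
  expect_error(nmr_catalog(tf), "unknown biomarkers")

  bad2 <- the_catalog[the_catalog$tier != "ratio", ]
  tf2 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(as_tibble(bad2), tf2)
  expect_error(nmr_catalog(tf2), "tier counts")
})

test_that("subclass lipid arithmetic follows the sum rules", {
  x <- constant_input(1, value = 0) # start from zeros, then set one subclass
  x$XXL_VLDL_FC <- 1; x$XXL_VLDL_CE <- 2
  x$XXL_VLDL_PL <- 3; x$XXL_VLDL_TG <- 4
  x$Omega_3 <- 0.4; x$Omega_6 <- 1.6
  full <- nmr_rederive(x)
  expect_equal(full$XXL_VLDL_L, 10)  # FC + CE + PL + TG
  expect_equal(full$XXL_VLDL_C, 3)   # FC + CE
  expect_equal(full$PUFA, 2.0)       # omega-3 + omega-6
  expect_equal(full$Omega_3_pct_PUFA, 20)
  expect_equal(full$Omega_6_pct_PUFA, 80)
})

test_that("missing operands and zero denominators propagate to missing", {
  x <- constant_input(3)
  x$Ile[2] <- NA
  x$Total_FA <- NULL # not needed: rederive recomputes it anyway
  x$MUFA[3] <- 0
  x$PUFA_input_ignored <- 1
  full <- nmr_rederive(x)
  expect_true(is.na(full$Total_BCAA[2]))
  expect_false(anyNA(full$Total_BCAA[c(1, 3)]))
  expect_true(is.na(full$PUFA_by_MUFA[3])) # x/0 -> missing
  audit <- attr(full, "zero_denominator_counts")
  expect_equal(audit$n_zero_denominator[audit$biomarker == "PUFA_by_MUFA"], 1L)
})

test_that("a missing non-derived input column is a fatal, named error", {
  x <- constant_input(2)
  x$Gly <- NULL
  expect_error(nmr_rederive(x), "Gly")
})

test_that("extended ratios have the documented structure", {
  ext <- the_catalog[the_catalog$tier == "extended_ratio", ]
  expect_equal(nrow(ext), 76)
  # 20 lipid fractions at class/serum level
  expect_equal(sum(ext$group == "extended lipid fractions"), 20)
  # 36 cholesterol percentages + 18 FC:CE ratios
  expect_equal(sum(ext$group == "extended cholesterol fractions"), 54)
  expect_equal(sum(grepl("_FC_by_CE$", ext$name)), 18)
  expect_equal(sum(ext$group == "extended fatty acid fractions"), 2)

  x <- constant_input(1)
  x$HDL_FC_stub <- NULL
  # FC = 1, CE = 3 at one subclass level
  x$S_HDL_FC <- 1; x$S_HDL_CE <- 3
  out <- nmr_extended_ratios(x)
  expect_equal(ncol(out), 1 + 76)
  expect_equal(out$S_HDL_FC_pct_C, 25)
  expect_equal(out$S_HDL_CE_pct_C, 75)
  expect_equal(out$S_HDL_FC_by_CE, 1 / 3)
})

test_that("sum and percentage closure hold on random inputs", {
  set.seed(19)
  n <- 25
  x <- bind_cols(
    tibble(sample_id = as.character(seq_len(n))),
    as_tibble(setNames(
      lapply(non_derived_names, function(...) rlnorm(n, 0, 1)),
      non_derived_names))
  )
  full <- nmr_rederive(x)
  formulas <- attr(the_catalog, "formulas")
  for (nm in the_catalog$name[the_catalog$tier == "composite"]) {
    parts <- Reduce(`+`, lapply(formulas[[nm]]$args, function(a) full[[a]]))
    expect_equal(full[[nm]], parts, tolerance = 1e-12)
  }
  for (lv in c("Total", "VLDL", "LDL", "HDL")) {
    fam <- rowSums(cbind(full[[paste0(lv, "_PL_pct")]],
                         full[[paste0(lv, "_TG_pct")]],
                         full[[paste0(lv, "_FC_pct")]],
                         full[[paste0(lv, "_CE_pct")]]))
    expect_equal(fam, rep(100, n), tolerance = 1e-9)
    expect_equal(full[[paste0(lv, "_FC_pct_C")]] + full[[paste0(lv, "_CE_pct_C")]],
                 rep(100, n), tolerance = 1e-9)
  }
  expect_equal(full$Omega_3_pct_PUFA + full$Omega_6_pct_PUFA, rep(100, n),
               tolerance = 1e-9)

  # idempotence: re-deriving from the derived table's non-derived columns
  # reproduces the table exactly
  again <- nmr_rederive(full[c("sample_id", non_derived_names)])
  expect_identical(as.data.frame(again), as.data.frame(full))
})
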