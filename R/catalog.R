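#' Load the biomarker catalog
#'
#' Reads the biomarker definition file shipped with the package (or a
#' user-supplied replacement) and validates it. The catalog encodes the
#' full dependency structure of the NMR metabolic biomarker set: 107
#' non-derived biomarkers, 61 composite biomarkers (sums of two or more
#' other biomarkers, e.g. total cholesterol = free + esterified
#' cholesterol), 81 ratios available in the original data, and 76
#' extended ratios (class and serum lipid fractions, cholesterol
#' fractions, free:esterified cholesterol ratios, and the omega-3/omega-6
#' split of polyunsaturated fatty acids).
#'
#' The definition file is tab-separated with columns `name`,
#' `display_name`, `units`, `tier` and `formula`. Formulas use a small
#' infix grammar over other biomarker names:
#' * sums: `A + B + C` (composite biomarkers),
#' * quotients: `A / B` (ratios),
#' * percentages: `A / B * 100`.
#'
#' @param path Path to a catalog TSV. Defaults to the file shipped with
#'   the package.
#' @return A tibble with one row per biomarker definition and class
#'   `nmr_catalog`. Parsed formulas and a topological evaluation order
#'   are stored as attributes.
#' @examples
#' cat325 <- nmr_catalog()
#' dplyr::count(cat325, tier)
#' @export
nmr_catalog <- function(path = NULL) {
  path <- path %||% system.file("extdata", "biomarker_catalog.tsv",
                                package = "nmrplateqc", mustWork = TRUE)
  defs <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                          progress = FALSE)
  defs$formula[is.na(defs$formula)] <- ""
  validate_catalog(defs)
}

parse_formula <- function(x) {
  if (x == "") return(NULL)
  if (grepl("*", x, fixed = TRUE)) {
    parts <- strsplit(sub(" \\* 100$", "", x), " / ", fixed = FALSE)[[1]]
    return(list(op = "percent", args = parts))
  }
  if (grepl("/", x, fixed = TRUE)) {
    return(list(op = "quotient", args = strsplit(x, " / ")[[1]]))
  }
  list(op = "sum", args = strsplit(x, " + ", fixed = TRUE)[[1]])
}

validate_catalog <- function(defs) {
  problems <- character()
  required_cols <- c("name", "display_name", "units", "tier", "formula")
  missing_cols <- setdiff(required_cols, names(defs))
  if (length(missing_cols)) {
    abort(paste0("malformed catalog: missing columns ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(defs$name)) {
    problems <- c(problems, paste0("duplicated names: ",
      paste(unique(defs$name[duplicated(defs$name)]), collapse = ", ")))
  }
  tiers <- c("non_derived", "composite", "ratio", "extended_ratio")
  bad_tier <- setdiff(unique(defs$tier), tiers)
  if (length(bad_tier)) {
    problems <- c(problems, paste0("unknown tiers: ", paste(bad_tier, collapse = ", ")))
  }
  counts <- table(factor(defs$tier, levels = tiers))
  expected <- c(non_derived = 107L, composite = 61L, ratio = 81L,
                extended_ratio = 76L)
  if (!identical(as.integer(counts), unname(expected))) {
    problems <- c(problems, paste0(
      "tier counts ", paste(counts, collapse = "/"),
      " do not match the expected 107/61/81/76"))
  }
  # formula presence must match tier
  has_formula <- defs$formula != ""
  if (any(has_formula & defs$tier == "non_derived")) {
    problems <- c(problems, "non_derived definitions with a formula")
  }
  if (any(!has_formula & defs$tier != "non_derived")) {
    problems <- c(problems, paste0("derived definitions without a formula: ",
      paste(defs$name[!has_formula & defs$tier != "non_derived"], collapse = ", ")))
  }
  formulas <- map(set_names(defs$formula, defs$name), parse_formula)
  # referenced names exist
  referenced <- unique(unlist(map(formulas, "args")))
  unknown <- setdiff(referenced, defs$name)
  if (length(unknown)) {
    problems <- c(problems, paste0("formulas reference unknown biomarkers: ",
                                   paste(unknown, collapse = ", ")))
  }
  # composites are sums of >= 2 names
  comp <- defs$name[defs$tier == "composite"]
  bad_comp <- comp[map_chr(formulas[comp], "op") != "sum" |
                     lengths(map(formulas[comp], "args")) < 2]
  if (length(bad_comp)) {
    problems <- c(problems, paste0("composites that are not sums of >= 2 names: ",
                                   paste(bad_comp, collapse = ", ")))
  }
  topo <- tryCatch(topological_order(formulas, defs$name),
                   error = function(e) {
                     problems <<- c(problems, conditionMessage(e))
                     NULL
                   })
  if (length(problems)) {
    abort(paste0("malformed catalog:\n", paste0("- ", problems, collapse = "\n")))
  }
  out <- as_tibble(defs)
  attr(out, "formulas") <- formulas
  attr(out, "topo_order") <- topo
  class(out) <- c("nmr_catalog", class(out))
  out
}

set_names <- function(x, nm) stats::setNames(x, nm)

# Kahn topological sort over the formula dependency graph; errors on cycles
topological_order <- function(formulas, names_all) {
  deps <- map(formulas, function(f) if (is.null(f)) character() else f$args)
  indeg <- lengths(map(deps, setdiff, character()))
  remaining <- set_names(deps, names_all)
  order <- character()
  resolved <- character()
  pending <- names_all
  repeat {
    ready <- pending[map_lgl(remaining[pending], function(d) all(d %in% resolved))]
    if (!length(ready)) break
    order <- c(order, ready)
    resolved <- c(resolved, ready)
    pending <- setdiff(pending, ready)
  }
  if (length(pending)) {
    abort(paste0("dependency graph contains a cycle involving: ",
                 paste(head(pending, 10), collapse = ", ")))
  }
  order
}

catalog_formulas <- function(catalog) attr(catalog, "formulas")

#' Re-derive composite biomarkers, ratios and extended ratios
#'
#' Recomputes every derived biomarker from the 107 non-derived
#' biomarkers by evaluating the catalog formulas in dependency order:
#' composites (sums) first, then ratios, then extended ratios. Any
#' formula with a missing operand yields a missing value, as does any
#' quotient with a zero denominator (0/0 and x/0 are both set missing
#' and counted in the audit attribute).
#'
#' Derived columns already present in `data` are ignored and replaced by
#' their recomputed values; identifier and other non-biomarker columns
#' are carried through unchanged.
#'
#' @param data A data frame containing at least the 107 non-derived
#'   biomarker columns (plus any identifier columns).
#' @param catalog An [nmr_catalog()] object; defaults to the shipped one.
#' @param tiers Which derived tiers to compute.
#' @return A tibble with the non-biomarker columns of `data` followed by
#'   all 325 biomarkers in catalog order (when all tiers are requested).
#'   The attribute `zero_denominator_counts` is a tibble counting, per
#'   ratio, rows set missing because of a zero denominator.
#' @examples
#' cat325 <- nmr_catalog()
#' nd <- cat325$name[cat325$tier == "non_derived"]
#' x <- tibble::as_tibble(setNames(as.list(rep(1, length(nd))), nd))
#' full <- nmr_rederive(x)
#' full$Total_BCAA # Ile + Leu + Val = 3
#' @export
nmr_rederive <- function(data, catalog = NULL,
                         tiers = c("composite", "ratio", "extended_ratio")) {
  catalog <- catalog %||% nmr_catalog()
  tiers <- match.arg(tiers, several.ok = TRUE)
  non_derived <- catalog$name[catalog$tier == "non_derived"]
  missing_nd <- setdiff(non_derived, names(data))
  if (length(missing_nd)) {
    abort(paste0("missing required non-derived biomarker column(s): ",
                 paste(missing_nd, collapse = ", ")))
  }
  id_cols <- setdiff(names(data), catalog$name)
  n <- nrow(data)
  values <- matrix(NA_real_, nrow = n, ncol = nrow(catalog),
                   dimnames = list(NULL, catalog$name))
  for (nm in non_derived) values[, nm] <- as.numeric(data[[nm]])
  formulas <- catalog_formulas(catalog)
  want <- c("non_derived", tiers)
  tier_of <- set_names(catalog$tier, catalog$name)
  n_zero_den <- integer()
  for (nm in attr(catalog, "topo_order")) {
    f <- formulas[[nm]]
    if (is.null(f) || !(tier_of[[nm]] %in% tiers)) next
    if (f$op == "sum") {
      values[, nm] <- Reduce(`+`, lapply(f$args, function(a) values[, a]))
    } else {
      num <- values[, f$args[1]]
      den <- values[, f$args[2]]
      out <- num / den
      zero_den <- !is.na(den) & den == 0
      out[zero_den] <- NA_real_
      if (f$op == "percent") out <- out * 100
      out[is.infinite(out) | is.nan(out)] <- NA_real_
      values[, nm] <- out
      n_zero_den[nm] <- sum(zero_den)
    }
  }
  keep_cols <- catalog$name[catalog$tier %in% want]
  out <- bind_cols(data[id_cols], as_tibble(values[, keep_cols, drop = FALSE]))
  attr(out, "zero_denominator_counts") <-
    tibble(biomarker = names(n_zero_den), n_zero_denominator = unname(n_zero_den))
  out
}

#' Derive the 76 extended biomarker ratios
#'
#' Computes only the extended-ratio tier: 20 lipid fractions
#' (phospholipids, triglycerides, free cholesterol, cholesteryl esters
#' and total cholesterol as a percentage of total lipids, for total
#' serum, VLDL, LDL and HDL), 36 cholesterol fractions (free and
#' esterified cholesterol as a percentage of total cholesterol at 18
#' levels: serum, 3 classes, 14 subclasses), the 18 corresponding
#' free:esterified cholesterol ratios, and the omega-3 and omega-6
#' percentages of polyunsaturated fatty acids.
#'
#' @inheritParams nmr_rederive
#' @return A tibble with the non-biomarker columns of `data` plus the 76
#'   extended ratio columns.
#' @export
nmr_extended_ratios <- function(data, catalog = NULL) {
  catalog <- catalog %||% nmr_catalog()
  full <- nmr_rederive(data, catalog)
  id_cols <- setdiff(names(data), catalog$name)
  ext <- catalog$name[catalog$tier == "extended_ratio"]
  out <- bind_cols(full[id_cols], full[ext])
  attr(out, "zero_denominator_counts") <- attr(full, "zero_denominator_counts")
  out
}

#' @export
glance.nmr_catalog <- function(x, ...) {
  tibble(
    n_definitions = nrow(x),
    n_non_derived = sum(x$tier == "non_derived"),
    n_composite = sum(x$tier == "composite"),
    n_ratio = sum(x$tier == "ratio"),
    n_extended_ratio = sum(x$tier == "extended_ratio")
  )
}
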