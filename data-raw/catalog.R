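# Builds inst/extdata/biomarker_catalog.tsv, the shipped biomarker
# definition file. Formula grammar: sums "A + B + ...", quotients "A / B",
# percentages "A / B * 100". Re-run after editing and commit the TSV.
library(tibble)
library(dplyr)
library(purrr)
library(readr)

sc <- tribble(
  ~code,       ~label,                                     ~class,
  "XXL_VLDL",  "chylomicrons and extremely large VLDL",    "VLDL",
  "XL_VLDL",   "very large VLDL",                          "VLDL",
  "L_VLDL",    "large VLDL",                               "VLDL",
  "M_VLDL",    "medium VLDL",                              "VLDL",
  "S_VLDL",    "small VLDL",                               "VLDL",
  "XS_VLDL",   "very small VLDL",                          "VLDL",
  "IDL",       "IDL",                                      "IDL",
  "L_LDL",     "large LDL",                                "LDL",
  "M_LDL",     "medium LDL",                               "LDL",
  "S_LDL",     "small LDL",                                "LDL",
  "XL_HDL",    "very large HDL",                           "HDL",
  "L_HDL",     "large HDL",                                "HDL",
  "M_HDL",     "medium HDL",                               "HDL",
  "S_HDL",     "small HDL",                                "HDL"
)

comp <- tribble(
  ~suffix, ~clabel,                  ~units,
  "P",     "particle concentration", "mmol/L",
  "L",     "total lipids",           "mmol/L",
  "PL",    "phospholipids",          "mmol/L",
  "C",     "total cholesterol",      "mmol/L",
  "CE",    "cholesteryl esters",     "mmol/L",
  "FC",    "free cholesterol",       "mmol/L",
  "TG",    "triglycerides",          "mmol/L"
)

def <- function(name, display_name, units, tier, group, formula = "") {
  tibble(name = name, display_name = display_name, units = units,
         tier = tier, group = group, formula = formula)
}

rows <- list()

## ---- lipoprotein subclass concentrations (14 x 7) ----
for (i in seq_len(nrow(sc))) {
  s <- sc$code[i]; lab <- sc$label[i]
  for (j in seq_len(nrow(comp))) {
    m <- comp$suffix[j]
    nm <- paste0(s, "_", m)
    disp <- paste0(comp$clabel[j], " in ", lab)
    if (m == "C") {
      rows[[length(rows) + 1]] <- def(nm, disp, "mmol/L", "composite",
        "lipoprotein subclass lipids",
        paste0(s, "_FC + ", s, "_CE"))
    } else if (m == "L") {
      rows[[length(rows) + 1]] <- def(nm, disp, "mmol/L", "composite",
        "lipoprotein subclass lipids",
        paste0(s, "_FC + ", s, "_CE + ", s, "_PL + ", s, "_TG"))
    } else {
      rows[[length(rows) + 1]] <- def(nm, disp, comp$units[j], "non_derived",
        "lipoprotein subclass lipids")
    }
  }
}

## ---- class and serum totals (4 x 7 composites) ----
class_members <- list(
  VLDL = sc$code[sc$class == "VLDL"],
  LDL  = sc$code[sc$class == "LDL"],
  HDL  = sc$code[sc$class == "HDL"]
)
for (m in comp$suffix) {
  for (cl in names(class_members)) {
    nm <- paste0(cl, "_", m)
    disp <- paste0(comp$clabel[comp$suffix == m], " in ", cl)
    rows[[length(rows) + 1]] <- def(nm, disp, "mmol/L", "composite",
      "lipoprotein class lipids",
      paste(paste0(class_members[[cl]], "_", m), collapse = " + "))
  }
  nm <- paste0("Total_", m)
  disp <- paste0("total serum ", comp$clabel[comp$suffix == m])
  rows[[length(rows) + 1]] <- def(nm, disp, "mmol/L", "composite",
    "serum lipids",
    paste(paste0(c("VLDL", "IDL", "LDL", "HDL"), "_", m), collapse = " + "))
}

## ---- other cholesterol measures ----
rows[[length(rows) + 1]] <- def("non_HDL_C", "non-HDL cholesterol", "mmol/L",
  "composite", "cholesterol", "VLDL_C + IDL_C + LDL_C")
rows[[length(rows) + 1]] <- def("Remnant_C", "remnant cholesterol (non-HDL, non-LDL)",
  "mmol/L", "composite", "cholesterol", "VLDL_C + IDL_C")
rows[[length(rows) + 1]] <- def("Clinical_LDL_C", "clinical LDL cholesterol",
  "mmol/L", "non_derived", "cholesterol")

## ---- particle sizes ----
rows[[length(rows) + 1]] <- def("VLDL_size", "average diameter for VLDL particles",
  "nm", "non_derived", "lipoprotein particle sizes")
rows[[length(rows) + 1]] <- def("LDL_size", "average diameter for LDL particles",
  "nm", "non_derived", "lipoprotein particle sizes")
rows[[length(rows) + 1]] <- def("HDL_size", "average diameter for HDL particles",
  "nm", "non_derived", "lipoprotein particle sizes")

## ---- other lipids ----
rows[[length(rows) + 1]] <- def("Phosphoglyc", "phosphoglycerides", "mmol/L",
  "non_derived", "other lipids")
rows[[length(rows) + 1]] <- def("Cholines", "total cholines", "mmol/L",
  "non_derived", "other lipids")
rows[[length(rows) + 1]] <- def("Phosphatidylc", "phosphatidylcholines", "mmol/L",
  "non_derived", "other lipids")
rows[[length(rows) + 1]] <- def("Sphingomyelins", "sphingomyelins", "mmol/L",
  "non_derived", "other lipids")
rows[[length(rows) + 1]] <- def("TG_by_PG", "triglycerides to phosphoglycerides ratio",
  "ratio", "ratio", "other lipids", "Total_TG / Phosphoglyc")

## ---- apolipoproteins ----
rows[[length(rows) + 1]] <- def("ApoA1", "apolipoprotein A1", "g/L",
  "non_derived", "apolipoproteins")
rows[[length(rows) + 1]] <- def("ApoB", "apolipoprotein B", "g/L",
  "non_derived", "apolipoproteins")
rows[[length(rows) + 1]] <- def("ApoB_by_ApoA1", "apolipoprotein B to apolipoprotein A1 ratio",
  "ratio", "ratio", "apolipoproteins", "ApoB / ApoA1")

## ---- fatty acids ----
fa_nd <- tribble(
  ~name, ~disp,
  "Omega_3",      "omega-3 fatty acids",
  "Omega_6",      "omega-6 fatty acids",
  "MUFA",         "monounsaturated fatty acids",
  "SFA",          "saturated fatty acids",
  "LA",           "linoleic acid",
  "DHA",          "docosahexaenoic acid"
)
for (i in seq_len(nrow(fa_nd)))
  rows[[length(rows) + 1]] <- def(fa_nd$name[i], fa_nd$disp[i], "mmol/L",
    "non_derived", "fatty acids")
rows[[length(rows) + 1]] <- def("Unsaturation", "estimated degree of unsaturation",
  "degree", "non_derived", "fatty acids")
rows[[length(rows) + 1]] <- def("PUFA", "polyunsaturated fatty acids", "mmol/L",
  "composite", "fatty acids", "Omega_3 + Omega_6")
rows[[length(rows) + 1]] <- def("Total_FA", "total fatty acids", "mmol/L",
  "composite", "fatty acids", "SFA + MUFA + PUFA")
for (x in c("Omega_3", "Omega_6", "PUFA", "MUFA", "SFA", "LA", "DHA"))
  rows[[length(rows) + 1]] <- def(paste0(x, "_pct"),
    paste0(x, " as percentage of total fatty acids"), "%", "ratio",
    "fatty acid percentages", paste0(x, " / Total_FA * 100"))
rows[[length(rows) + 1]] <- def("PUFA_by_MUFA",
  "polyunsaturated to monounsaturated fatty acid ratio", "ratio", "ratio",
  "fatty acid percentages", "PUFA / MUFA")
rows[[length(rows) + 1]] <- def("Omega_6_by_Omega_3",
  "omega-6 to omega-3 fatty acid ratio", "ratio", "ratio",
  "fatty acid percentages", "Omega_6 / Omega_3")

## ---- amino acids ----
aa <- tribble(
  ~name, ~disp,
  "Ala", "alanine", "Gln", "glutamine", "Gly", "glycine", "His", "histidine",
  "Ile", "isoleucine", "Leu", "leucine", "Val", "valine",
  "Phe", "phenylalanine", "Tyr", "tyrosine"
)
for (i in seq_len(nrow(aa)))
  rows[[length(rows) + 1]] <- def(aa$name[i], aa$disp[i], "mmol/L",
    "non_derived", "amino acids")
rows[[length(rows) + 1]] <- def("Total_BCAA", "total branched-chain amino acids",
  "mmol/L", "composite", "amino acids", "Ile + Leu + Val")

## ---- glycolysis, ketones, fluid balance, inflammation ----
misc <- tribble(
  ~name, ~disp, ~group,
  "Glucose",      "glucose",            "glycolysis related metabolites",
  "Lactate",      "lactate",            "glycolysis related metabolites",
  "Pyruvate",     "pyruvate",           "glycolysis related metabolites",
  "Citrate",      "citrate",            "glycolysis related metabolites",
  "bOHbutyrate",  "3-hydroxybutyrate",  "ketone bodies",
  "Acetate",      "acetate",            "ketone bodies",
  "Acetoacetate", "acetoacetate",       "ketone bodies",
  "Acetone",      "acetone",            "ketone bodies",
  "Creatinine",   "creatinine",         "fluid balance",
  "GlycA",        "glycoprotein acetyls", "inflammation"
)
for (i in seq_len(nrow(misc)))
  rows[[length(rows) + 1]] <- def(misc$name[i], misc$disp[i], "mmol/L",
    "non_derived", misc$group[i])
rows[[length(rows) + 1]] <- def("Albumin", "albumin", "g/L",
  "non_derived", "fluid balance")

## ---- subclass percentage ratios (14 x 5) ----
for (i in seq_len(nrow(sc))) {
  s <- sc$code[i]; lab <- sc$label[i]
  for (m in c("PL", "C", "CE", "FC", "TG")) {
    clabel <- comp$clabel[comp$suffix == m]
    rows[[length(rows) + 1]] <- def(paste0(s, "_", m, "_pct"),
      paste0(clabel, " as percentage of total lipids in ", lab), "%",
      "ratio", "lipoprotein subclass percentages",
      paste0(s, "_", m, " / ", s, "_L * 100"))
  }
}

## ---- extended ratios: class/serum lipid fractions (4 x 5 = 20) ----
lvl4 <- c(Total = "total serum lipids", VLDL = "VLDL", LDL = "LDL", HDL = "HDL")
for (lv in names(lvl4)) {
  for (m in c("PL", "TG", "FC", "CE", "C")) {
    clabel <- comp$clabel[comp$suffix == m]
    rows[[length(rows) + 1]] <- def(paste0(lv, "_", m, "_pct"),
      paste0(clabel, " as percentage of total lipids in ", lvl4[[lv]]), "%",
      "extended_ratio", "extended lipid fractions",
      paste0(lv, "_", m, " / ", lv, "_L * 100"))
  }
}

## ---- extended ratios: cholesterol fractions and FC:CE (18 levels) ----
lvl18 <- c(names(lvl4), sc$code)
lab18 <- c(unname(lvl4), sc$label)
for (i in seq_along(lvl18)) {
  lv <- lvl18[i]
  rows[[length(rows) + 1]] <- def(paste0(lv, "_FC_pct_C"),
    paste0("free cholesterol as percentage of total cholesterol in ", lab18[i]),
    "%", "extended_ratio", "extended cholesterol fractions",
    paste0(lv, "_FC / ", lv, "_C * 100"))
  rows[[length(rows) + 1]] <- def(paste0(lv, "_CE_pct_C"),
    paste0("esterified cholesterol as percentage of total cholesterol in ", lab18[i]),
    "%", "extended_ratio", "extended cholesterol fractions",
    paste0(lv, "_CE / ", lv, "_C * 100"))
  rows[[length(rows) + 1]] <- def(paste0(lv, "_FC_by_CE"),
    paste0("free to esterified cholesterol ratio in ", lab18[i]),
    "ratio", "extended_ratio", "extended cholesterol fractions",
    paste0(lv, "_FC / ", lv, "_CE"))
}

## ---- extended ratios: PUFA split (2) ----
rows[[length(rows) + 1]] <- def("Omega_3_pct_PUFA",
  "omega-3 as percentage of polyunsaturated fatty acids", "%",
  "extended_ratio", "extended fatty acid fractions", "Omega_3 / PUFA * 100")
rows[[length(rows) + 1]] <- def("Omega_6_pct_PUFA",
  "omega-6 as percentage of polyunsaturated fatty acids", "%",
  "extended_ratio", "extended fatty acid fractions", "Omega_6 / PUFA * 100")

catalog <- bind_rows(rows)
stopifnot(!anyDuplicated(catalog$name))
print(table(catalog$tier))
stopifnot(identical(as.integer(table(catalog$tier)[c("non_derived", "composite", "ratio", "extended_ratio")]),
                    c(107L, 61L, 81L, 76L)))
write_tsv(catalog, file.path("inst", "extdata", "biomarker_catalog.tsv"))
cat("wrote", nrow(catalog), "definitions\n")
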