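# Modification vocabulary accepted at ingestion. Only the phospho types
# switch a PSM into the STYP stream; the rest ride along as annotation.
MOD_TYPES <- c("phospho_S", "phospho_T", "phospho_Y",
               "acetyl", "oxidation_M", "loss_water", "loss_ammonia")

PHOSPHO_TYPES <- c("phospho_S", "phospho_T", "phospho_Y")

AA_20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Kyte-Doolittle hydropathy scale, kcal/mol-free index units
KD_SCALE <- c(A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
              Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
              L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
              S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2)

PSM_COLUMNS <- c("spectrum_id", "sample_id", "fraction", "treatment_id",
                 "peptide", "modifications", "charge", "engine", "score",
                 "precursor_intensity", "protein_accession", "gene_symbol")

FREQ_COLUMNS <- c("gene_symbol", "stream", "count_case", "count_control",
                  "corrected_control", "delta", "chi2", "pvalue", "qvalue")

TREATMENT_LABELS <- c(
  "Alzheimer normal",
  "Alzheimer normal control STYP",
  "Alzheimer dementia",
  "Alzheimer dementia STYP",
  "Cancer breast",
  "Cancer breast STYP",
  "Cancer control",
  "Cancer control STYP",
  "Cancer ovarian",
  "Cancer ovarian STYP",
  "Ice cold",
  "Ice cold STYP",
  "Heart attack arterial",
  "Heart attack arterial STYP",
  "Heart attack normal control",
  "Heart attack normal control STYP",
  "Heart attack",
  "Heart attack STYP",
  "Multiple sclerosis normal control",
  "Multiple sclerosis normal control STYP",
  "Multiple sclerosis",
  "Multiple sclerosis STYP",
  "Sepsis",
  "Sepsis STYP",
  "Sepsis normal control",
  "Sepsis normal control STYP")
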