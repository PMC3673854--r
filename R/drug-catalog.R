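#' Fall-risk medication catalog
#'
#' The 41 fall-associated prescription medications used by the default
#' synthetic cohort, with the number of users observed in the source cohort
#' (used here as a relative popularity weight) and the published
#' correspondence-analysis score, used by the generator as a per-drug fall
#' hazard weight. Sedative-hypnotics, antidepressants and antipsychotics
#' dominate the list, as is typical of fall-risk-increasing-drug catalogs.
#'
#' @return A data.frame with columns `name`, `n_users` and `hazard`.
#' @examples
#' head(drug_catalog())
#' @export
drug_catalog <- function() {
  data.frame(
    name = c(
      "PHENOBARBITAL", "CLOMIPRAMINE", "METHADONE", "IMIPRAMINE", "MORPHINE",
      "PRIMIDONE", "HYDROCODONE", "DIAZEPAM", "CHLORDIAZEPOXIDE",
      "RBAMAZEPINE", "OXAZEPAM", "MIRTAZAPINE", "AMITRIPTYLINE", "ALPRAZOLAM",
      "CLONAZEPAM", "BUSPIRONE", "OXYCODONE", "GABAPENTIN", "DIGOXIN",
      "MEPROBAMATE", "LORAZEPAM", "DISOPYRAMIDE", "NEFAZODONE", "PHENYTOIN",
      "TEMAZEPAM", "ESTAZOLAM", "PAROXETINE", "CHLORPROMAZINE", "TRIAZOLAM",
      "FLUOXETINE", "BACLOFEN", "DESIPRAMINE", "HYDROMORPHONE", "HALOPERIDOL",
      "CITALOPRAM", "TRAZODONE", "BUPROPION", "DOXEPIN", "PERPHENAZINE",
      "AMOXAPINE", "THIORIDAZINE"
    ),
    n_users = c(
      8L, 8L, 7L, 17L, 36L, 43L, 46L, 128L, 45L, 37L, 23L, 86L, 180L, 1297L,
      368L, 124L, 206L, 210L, 272L, 44L, 572L, 9L, 6L, 35L, 1470L, 179L,
      338L, 11L, 16L, 310L, 25L, 6L, 7L, 11L, 60L, 234L, 20L, 83L, 19L, 7L,
      8L
    ),
    hazard = c(
      -0.690, -0.690, -0.690, -0.423, -0.423, -0.405, -0.262, -0.234,
      -0.225, -0.187, -0.155, -0.124, -0.095, -0.094, -0.077, -0.072,
      -0.054, -0.051, -0.038, -0.010, 0.009, 0.023, 0.023, 0.023, 0.030,
      0.045, 0.049, 0.165, 0.227, 0.241, 0.379, 0.379, 0.379, 0.379, 0.414,
      0.455, 0.498, 0.580, 0.593, 1.449, 1.449
    ),
    stringsAsFactors = FALSE
  )
}
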