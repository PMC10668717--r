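# construct sign records with sensible defaults for tests
sign_row <- function(sign_id = "S1", date = "2015-12-01", x = 100, y = 100,
                     country = "FR", evidence_type = "dna_sample", ...) {
  row <- data.frame(sign_id = sign_id, date = as.Date(date), x = x, y = y,
                    country = country, evidence_type = evidence_type,
                    stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) row[[nm]] <- extra[[nm]]
  row
}

sign_table <- function(...) {
  rows <- list(...)
  cols <- unique(unlist(lapply(rows, names)))
  filled <- lapply(rows, function(r) {
    for (nm in setdiff(cols, names(r))) r[[nm]] <- NA
    r[, cols]
  })
  do.call(rbind, filled)
}

# a C1 DNA sign usable as unit evidence
dna_sign <- function(sign_id, x, y, genotype, sex, date = "2015-12-01",
                     pedigree = NULL, age = "adult") {
  sign_row(sign_id = sign_id, date = date, x = x, y = y,
           evidence_type = "dna_sample", dna_confirmed_wolf = TRUE,
           genotype_label = genotype, genotype_sex = sex, age_class = age,
           pedigree_id = if (is.null(pedigree)) NA_character_ else pedigree)
}

rank_category <- function(cat) {
  unname(c(discarded = 0, C3 = 1, C2 = 2, C1 = 3)[cat])
}
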