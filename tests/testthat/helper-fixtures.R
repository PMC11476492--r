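# shared fixture builders; everything is generated in code, no stored data

# small labelled cohort with optional overrides of the generator spec
tiny_cohort <- function(n_cases = 30, n_controls = 90, missing_rate = 0.25,
                        seed = 1, ...) {
  generate_cohort(cohort_spec(n_cases = n_cases, n_controls = n_controls,
                              missing_rate = missing_rate, seed = seed, ...))
}

# encode + impute + normalize in one go (training role)
prep <- function(table, seed = 1) {
  suppressWarnings({
    enc <- encode(table)
    imp <- fit_imputer(enc, seed = seed)
    fit_normalizer(impute_train(enc, imp))
  })
}

# hand-built encoded object with full 22-column schema; `values` overrides
# individual columns, remaining columns are filled with benign constants plus
# jitter so nothing is constant unless asked for
fake_encoded <- function(n, label = NULL, values = list(), jitter_seed = 99) {
  feats <- perisk:::FEATURES_22
  set.seed(jitter_seed)
  x <- matrix(rnorm(n * length(feats), 50, 5), n, length(feats),
              dimnames = list(NULL, feats))
  x[, "height"] <- 1.6
  x[, grep("^eth_", feats)] <- 0
  x[, "eth_Han"] <- 1
  x[, "gestational_day"] <- 100
  for (nm in names(values)) x[, nm] <- values[[nm]]
  x <- perisk:::derive_features(x)
  structure(list(x = x,
                 label = if (!is.null(label)) factor(label, levels = c("control", "case")),
                 platform = NULL, normalizer = NULL),
            class = "perisk_encoded")
}

maskable_cols <- function(table) setdiff(names(table), perisk:::UNMASKABLE)

missing_fraction <- function(table) {
  cells <- unlist(table[maskable_cols(table)])
  mean(is.na(cells))
}
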