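# fixtures shared across test files; expensive objects are computed once per
# test run and cached here
.cache <- new.env(parent = emptyenv())

cell_model <- function() {
  if (is.null(.cache$model)) .cache$model <- self_fabricating_cell()
  .cache$model
}

cell_egms <- function() {
  if (is.null(.cache$egms)) .cache$egms <- egms(cell_model())
  .cache$egms
}

# EGMs in canonical (integer) scaling, for decomposition tests
cell_egms_raw <- function() {
  if (is.null(.cache$egms_raw))
    .cache$egms_raw <- egms(cell_model(), normalize_mu = NULL)
  .cache$egms_raw
}

cell_egvs <- function(mu = "1/2") {
  key <- paste0("egv_", mu)
  if (is.null(.cache[[key]])) .cache[[key]] <- egvs(cell_model(), mu)
  .cache[[key]]
}

cell_sweep <- function() {
  if (is.null(.cache$sweep))
    .cache$sweep <- sweep_mu(cell_model(), mu_min = 0.05,
                             mu_max_scan = 1.5, step = 0.05)
  .cache$sweep
}

egm_by_product <- function(es, species) {
  prod <- vapply(es$produced, paste, character(1), collapse = "+")
  es$flux[match(species, prod), ]
}
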