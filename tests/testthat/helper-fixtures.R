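# Shared fixture builders; everything is generated in code under fixed seeds.

random_sequence <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(SparsePPI:::STANDARD_RESIDUES, n, replace = TRUE),
        collapse = "")
}

# random normalised weighted-l1 instance (columns and query on the sphere)
random_l1_instance <- function(d, n, seed) {
  set.seed(seed)
  X <- matrix(rnorm(d * n), d, n)
  X <- sweep(X, 2, sqrt(colSums(X^2)), "/")
  y <- rnorm(d); y <- y / sqrt(sum(y^2))
  w <- runif(n, 0.4, 1)
  list(X = X, y = y, w = w)
}

# run the scipy reference solver on a list of instances; returns a data frame
# with columns objective, residual
run_weighted_l1_oracle <- function(instances, eps) {
  script <- system.file("tools", "weighted_l1_oracle.py", package = "SparsePPI")
  stopifnot(nzchar(script))
  payload <- lapply(instances, function(it) {
    list(d = nrow(it$X), n = ncol(it$X), X = as.numeric(it$X),
         y = it$y, w = it$w, eps = eps)
  })
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(payload, tmp, digits = NA, auto_unbox = TRUE)
  out <- system2("python", shQuote(script), stdin = tmp, stdout = TRUE,
                 stderr = FALSE)
  jsonlite::fromJSON(paste(out, collapse = ""))
}

# tiny protein/pair dataset for fast harness tests
tiny_dataset <- function(seed = 11) {
  generate_synthetic(n_proteins = 40, n_positive = 20, n_negative = 20,
                     seed = seed)
}
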