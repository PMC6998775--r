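# Run code with a temporary RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# stable 6-significant-digit text for report files
fmt_num <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.6g", x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# named list of crystal_datasets keyed by crystal_id, sorted by id
as_dataset_list <- function(datasets) {
  if (inherits(datasets, "crystal_dataset")) datasets <- list(datasets)
  ids <- vapply(datasets, function(d) d$crystal_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate crystal_id in dataset collection")
  datasets <- datasets[order(ids)]
  names(datasets) <- sort(ids)
  datasets
}
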