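# Shared fixture builders (all generated in code; no files on disk).

std_dataset <- function(gen) {
  d <- gen$data
  d$blocks <- lapply(d$blocks, center_scale)
  d
}

micro_std <- function() {
  me <- suppressMessages(worked_micro_example())
  list(data = std_dataset(me), truth = me$truth)
}

# Tiny two-block dataset from explicit matrices (already named/aligned).
tiny_dataset <- function(xa, xb, y, modality = "quantitative") {
  n <- nrow(xa)
  subjects <- sprintf("S%02d", seq_len(n))
  rownames(xa) <- rownames(xb) <- subjects
  if (is.null(colnames(xa))) colnames(xa) <- paste0("a", seq_len(ncol(xa)))
  if (is.null(colnames(xb))) colnames(xb) <- paste0("b", seq_len(ncol(xb)))
  names(y) <- subjects
  suppressMessages(
    multiomics_dataset(list(A = xa, B = xb), y, modality = modality))
}

# Deterministic permutation of a vector (fixed seed, RNG state restored).
with_seed_perm <- function(v, seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  v[sample.int(length(v))]
}

prefixed_planted <- function(gen) {
  unlist(Map(function(lab, f) paste(lab, f, sep = ":"),
             names(gen$truth$planted), gen$truth$planted), use.names = FALSE)
}
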