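#' @keywords internal
"_PACKAGE"

# Stage offsets for fanning a single global seed out to the pipeline stages.
# Offsets are fixed so that a run is fully determined by one integer.
.stage_offsets <- c(
  rr = 101L, ecg = 202L, histo = 303L, weights = 404L, stats = 505L
)

#' Derive a per-stage seed from a global seed
#'
#' A single global seed is fanned out to the pipeline stages by fixed
#' integer offsets, so that one integer determines the whole run while
#' stages stay statistically decoupled.
#'
#' @param seed integer global seed.
#' @param stage one of `"rr"`, `"ecg"`, `"histo"`, `"weights"`, `"stats"`.
#' @param k optional extra offset (e.g. animal index) added on top.
#' @return integer seed, kept below 2^31.
#' @export
stage_seed <- function(seed, stage = names(.stage_offsets), k = 0L) {
  stage <- match.arg(stage)
  s <- as.integer(seed) + .stage_offsets[[stage]] + as.integer(k)
  s %% .Machine$integer.max
}

# biased central sample moments m_k = mean((x - mean(x))^k)
central_moment <- function(x, k) {
  mean((x - mean(x))^k)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_bad_arg <- function(...) stop(..., call. = FALSE)

# 31-bit polynomial rolling hash of a character scalar; used to stamp
# configurations into output manifests without a cryptographic dependency.
fnv1a_hash <- function(txt) {
  bytes <- utf8ToInt(paste(txt, collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

# running maximum of x over a centred window of half-width w samples
running_max <- function(x, w) {
  n <- length(x)
  r <- x
  if (w < 1L) return(r)
  for (s in seq_len(w)) {
    r <- pmax(r,
              c(x[-seq_len(s)], rep(-Inf, s)),
              c(rep(-Inf, s), x[seq_len(n - s)]))
  }
  r
}
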