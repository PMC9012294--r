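# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards. All simulator randomness flows through this so a
# cohort never perturbs (or depends on) the session RNG.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive an independent substream seed from a master seed. Patients get
# disjoint substreams via fixed integer offsets so each patient is individually
# reproducible; `stage` separates draws within a patient (identities, pre
# repertoire, post repertoire, proportions, pre counts, post counts, ...).
# Kept strictly below 2^31 - 1 so it is always a valid R integer seed.
substream_seed <- function(seed, patient_index, stage) {
  s <- ((as.double(seed) %% 1000003) * 1009 +
          as.double(patient_index) * 131 + as.double(stage)) %% 2147483629
  as.integer(s)
}

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  invisible(x)
}
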