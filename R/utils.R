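# Internal helpers shared across modules.

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
# Every user-facing simulator takes one root seed; substreams are derived by
# offsetting it, keeping all offsets below .Machine$integer.max.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed %% 2147483647L))
  }
  force(expr)
}

# Derive a child seed from a root seed and a stream index, staying in 32-bit
# integer range.
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + stream * 7919) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_dosage <- function(x, what = "dosage matrix") {
  vals <- x[!is.na(x)]
  if (length(vals) && !all(vals %in% c(0, 1, 2))) {
    bad <- utils::head(setdiff(unique(vals), c(0, 1, 2)), 3)
    stop(sprintf("%s contains values outside {0, 1, 2, NA}: %s",
                 what, paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

# Align a named phenotype vector with the rows of a genotype matrix.
# Unnamed vectors of matching length are taken to be in row order.
align_phenotype <- function(geno, phenotype) {
  if (!is.null(names(phenotype))) {
    shared <- intersect(rownames(geno), names(phenotype))
    if (length(shared) < 3L) {
      stop("fewer than 3 RILs shared between genotypes and phenotype",
           call. = FALSE)
    }
    list(geno = geno[shared, , drop = FALSE], y = unname(phenotype[shared]))
  } else {
    if (length(phenotype) != nrow(geno)) {
      stop("unnamed phenotype length does not match number of RILs",
           call. = FALSE)
    }
    list(geno = geno, y = as.numeric(phenotype))
  }
}
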