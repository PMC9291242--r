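# Internal helpers shared across modules.

# Derive a stream-specific seed from a user seed. Keeps results < 2^31 so
# set.seed() always receives a valid 32-bit integer.
.deriveSeed <- function(seed, offset) {
    (abs(as.integer(seed)) %% 1999999L) * 1000L + (as.integer(offset) %% 1000L)
}

.checkScalarCount <- function(x, name, min = 1L) {
    if (length(x) != 1L || !is.finite(x) || x < min || x != round(x))
        stop(name, " must be a single integer >= ", min)
    as.integer(x)
}

# Standardize a vector; errors on zero variance.
.standardize <- function(x, name = "x") {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) stop(name, " has zero variance")
    (x - mean(x)) / s
}
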