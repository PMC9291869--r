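# Shared fixture builders. Everything is generated in code at test time.

# A small identity-scaled volume: value at voxel (i,j,k) settable directly.
makeVolume <- function(dims = c(10L, 10L, 10L), fill = 0,
                       semantics = "score",
                       voxel = 1, origin = c(0, 0, 0)) {
    aff <- diag(c(rep(voxel, 3), 1))
    aff[1:3, 4] <- origin
    StatVolume(grid = array(fill, dim = dims), affine = aff,
               semantics = semantics)
}

# Reference 8-corner weighted-sum interpolation, written independently of
# the package implementation (explicit weight products, no bit tricks).
oracleTrilinear <- function(grid, v) {
    d <- dim(grid)
    if (any(v < 0) || any(v > d - 1)) return(0)
    i0 <- pmax(pmin(floor(v), d - 2), 0)
    f <- v - i0
    total <- 0
    for (a in 0:1) for (b in 0:1) for (cc in 0:1) {
        w <- (if (a) f[1] else 1 - f[1]) *
             (if (b) f[2] else 1 - f[2]) *
             (if (cc) f[3] else 1 - f[3])
        total <- total + w * grid[i0[1] + a + 1, i0[2] + b + 1,
                                  i0[3] + cc + 1]
    }
    total
}

# Exhaustive two-sided Mann-Whitney p-value by enumerating all C(m+n, m)
# assignments of the pooled ranks to group a.
oracleRankSumP <- function(a, b) {
    pooled <- c(a, b)
    m <- length(a)
    r <- rank(pooled)
    obsU <- sum(r[seq_len(m)]) - m * (m + 1) / 2
    combs <- combn(length(pooled), m)
    U <- apply(combs, 2, function(idx)
        sum(r[idx]) - m * (m + 1) / 2)
    mid <- m * length(b) / 2
    # two-sided: double the smaller tail (as extreme or more), capped at 1
    if (obsU >= mid) {
        min(1, 2 * mean(U >= obsU))
    } else {
        min(1, 2 * mean(U <= obsU))
    }
}

# Reduced-scale generator config: one subcortical cluster holding 180 of
# 986 samples (the 180/800 design), no cortical samples.
subcorticalOnlyConfig <- function(seed, effectZ = c(OXTR = 0),
                                  coexpr = NULL) {
    syntheticConfig(
        seed = seed, nSubcortical = 986L, nCortical = 0L, nExcluded = 10L,
        clusters = data.frame(x = 10, y = 0, z = 0, radius_mm = 16,
                              compartment = "subcortex",
                              n_samples = 180L),
        effectZ = effectZ,
        coexprEffect = coexpr)
}

# A small full dataset for structural tests (fast to generate).
smallConfig <- function(seed = 1L, ...) {
    syntheticConfig(
        seed = seed, nSubcortical = 150L, nCortical = 120L,
        nExcluded = 20L,
        clusters = data.frame(x = c(10, -35), y = c(0, -35),
                              z = c(0, 25), radius_mm = c(16, 16),
                              compartment = c("subcortex", "cortex"),
                              n_samples = c(40L, 25L)),
        ...)
}

# Classification table built directly (bypassing any volume), for tests
# that exercise the statistics on constructed group memberships.
makeClassification <- function(ids, labels,
                               compartment = "subcortex") {
    n <- length(ids)
    data.frame(sample_id = ids,
               compartment = rep_len(compartment, n),
               interp_value = rep_len(NA_real_, n),
               label = rep_len(labels, n),
               excluded = rep_len(FALSE, n),
               excluded_reason = rep_len("", n),
               stringsAsFactors = FALSE)
}

# z-scored BrainExpression from a bare matrix (ids synthesized).
makeZExpr <- function(m, ids = sprintf("s%03d", seq_len(ncol(m)))) {
    colnames(m) <- ids
    BrainExpression(m, valueKind = "z_scored")
}
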