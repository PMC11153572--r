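# Internal helpers shared across modules.

# Sort rank for chromosome names: numeric chromosomes first in numeric order,
# then X, Y, MT, then anything else alphabetically. Accepts "chr" prefixes.
chrom_rank <- function(chrom) {
  core <- sub("^chr", "", as.character(chrom))
  num <- suppressWarnings(as.numeric(core))
  rank <- ifelse(!is.na(num), num,
    ifelse(core == "X", 23,
      ifelse(core == "Y", 24,
        ifelse(core %in% c("M", "MT"), 25, 26))))
  # stable tie-break for unknown names
  rank + match(core, sort(unique(core))) * 1e-6
}

is_autosome <- function(chrom) {
  core <- sub("^chr", "", as.character(chrom))
  !is.na(suppressWarnings(as.numeric(core)))
}

# Negative-binomial size parameter matching a target mean and sd
# (var = mu + mu^2/size). Falls back to Poisson-like (large size) when the
# requested sd is at or below the Poisson sd.
nbinom_size <- function(mean, sd) {
  v <- sd^2
  if (v <= mean) return(1e6)
  mean^2 / (v - mean)
}

# Beta shape parameters matching a target mean and sd, truncating the sd to
# keep both shapes positive.
beta_shapes <- function(mean, sd) {
  v <- min(sd^2, mean * (1 - mean) * 0.99)
  if (v <= 0) {
    return(c(shape1 = mean * 1e6, shape2 = (1 - mean) * 1e6))
  }
  common <- mean * (1 - mean) / v - 1
  c(shape1 = mean * common, shape2 = (1 - mean) * common)
}

# Half-open interval overlap in bp between [s1, e1) and [s2, e2).
overlap_bp <- function(s1, e1, s2, e2) {
  pmax(0, pmin(e1, e2) - pmax(s1, s2))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}
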