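## Evaluate expr under a temporary seed, restoring the caller's RNG state.
withLocalSeed <- function(seed, expr) {
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Contiguous runs of same-sign significant bins and their summed T mass.
## Returns data.frame(start, end, mass); Inf-valued t scores are allowed
## (zero-variance bins with a real mean difference).
.findClusters <- function(t, tcrit) {
  sig <- is.finite(t) & abs(t) > tcrit | is.infinite(t)
  if (!any(sig)) return(data.frame(start = integer(), end = integer(),
                                   mass = numeric()))
  lab <- sign(t) * sig        # -1, 0, 1 per bin
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0
  data.frame(start = starts[keep], end = ends[keep],
             mass = vapply(which(keep),
                           function(k) sum(t[starts[k]:ends[k]]), numeric(1)))
}

## Max |cluster mass| of one t-score vector (0 when no cluster forms).
## Hot path of the permutation null: avoids data.frame construction.
.maxClusterMass <- function(t, tcrit) {
  sig <- (is.finite(t) & abs(t) > tcrit) | is.infinite(t)
  if (!any(sig)) return(0)
  lab <- sign(t) * sig
  r <- rle(as.numeric(lab))
  keep <- r$values != 0
  if (!any(keep)) return(0)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  mx <- 0
  for (k in which(keep)) {
    m <- abs(sum(t[starts[k]:ends[k]]))
    if (m > mx) mx <- m
  }
  mx
}

## Pooled-variance (or Welch) two-sample t for column-matched matrices,
## computed from sufficient statistics. Returns list(t, df).
## Zero-variance bins: t = 0 when means agree, +/-Inf when they differ.
.colT <- function(meanA, meanB, ssA, ssB, nA, nB, welch = FALSE) {
  if (!welch) {
    df <- nA + nB - 2
    pv <- (ssA + ssB) / df
    se <- sqrt(pv * (1 / nA + 1 / nB))
  } else {
    vA <- ssA / (nA - 1); vB <- ssB / (nB - 1)
    se <- sqrt(vA / nA + vB / nB)
    num <- (vA / nA + vB / nB)^2
    den <- (vA / nA)^2 / (nA - 1) + (vB / nB)^2 / (nB - 1)
    df <- ifelse(den > 0, num / den, nA + nB - 2)
  }
  diff <- meanA - meanB
  t <- ifelse(se > 0, diff / se, ifelse(diff == 0, 0, Inf * sign(diff)))
  list(t = t, df = df)
}

## round numeric columns for deterministic CSV output
.roundCols <- function(df, digits = 6L) {
  for (j in seq_along(df))
    if (is.numeric(df[[j]])) df[[j]] <- signif(df[[j]], digits)
  df
}
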