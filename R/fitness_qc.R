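#' Vial-level quality control of fitness assays
#'
#' Male competition vials in which not all focal males were alive at the
#' end of the assay (`n_focal_alive < n_focal`) are dropped. Female
#' oviposition vials with fewer than 2 eggs, or in which the female died,
#' are dropped (exactly 2 eggs is retained). Lines that lose every vial in
#' both sexes are reported with a warning and excluded downstream.
#'
#' @param raw assay data.frame with columns `line`, `sex` ("M"/"F"),
#'   `block`, `vial`, `value`, `n_focal_alive`, `n_eggs`, `female_dead`.
#' @param n_focal expected number of focal males per vial (default 5).
#' @param min_eggs minimum egg count retained (default 2, "fewer than 2"
#'   removed).
#' @return The filtered data.frame.
#' @export
qc_vials <- function(raw, n_focal = 5L, min_eggs = 2) {
  male <- raw$sex == "M"
  drop <- (male & raw$n_focal_alive < n_focal) |
    (!male & (raw$n_eggs < min_eggs | raw$female_dead))
  drop[is.na(drop)] <- FALSE
  out <- raw[!drop, , drop = FALSE]
  lost <- setdiff(unique(raw$line), unique(out$line))
  if (length(lost))
    warning("line(s) lost all vials and are excluded: ",
            paste(lost, collapse = ", "))
  rownames(out) <- NULL
  out
}

#' Box-Cox transform and z-score fitness within a block
#'
#' The Box-Cox exponent is chosen per block by profile log-likelihood on a
#' grid (lambda in `[-5, 5]`, step 0.01); the transformed values are then
#' centred and scaled to unit SD within the block. Zeros are offset by half
#' the smallest nonzero value before transforming, so proportions of 0 are
#' handled without dropping vials.
#'
#' @param values positive (or zero, see offset) raw fitness values.
#' @param lambda_grid candidate exponents.
#' @return list with `z` (normalised values, mean 0 SD 1), `lambda`.
#' @export
boxcox_scale_block <- function(values, lambda_grid = seq(-5, 5, by = 0.01)) {
  if (length(unique(values)) < 2L)
    stop("constant values within block: Box-Cox exponent undefined")
  v <- values
  if (any(v <= 0)) {
    nz <- min(v[v > 0])
    v[v <= 0] <- v[v <= 0] + nz / 2
  }
  ll <- boxcox_loglik(v, lambda_grid)
  lambda <- lambda_grid[which.max(ll)]
  t <- if (abs(lambda) < 1e-12) log(v) else (v^lambda - 1) / lambda
  list(z = as.numeric(scale(t)), lambda = lambda)
}

# profile log-likelihood of the Box-Cox model over a lambda grid
boxcox_loglik <- function(v, grid) {
  n <- length(v)
  slog <- sum(log(v))
  vapply(grid, function(l) {
    t <- if (abs(l) < 1e-12) log(v) else (v^l - 1) / l
    s2 <- stats::var(t) * (n - 1) / n
    -n / 2 * log(s2) + (l - 1) * slog
  }, numeric(1))
}

#' Normalise an assay table within sex and block
#'
#' Applies [boxcox_scale_block()] to each sex-by-block cell of a QC'd assay
#' table; returns the table with a `z` column of scaled, centred fitness.
#'
#' @param qcd output of [qc_vials()].
#' @return data.frame with added `z` column; per-cell lambdas in
#'   attribute `"lambda"`.
#' @export
normalise_fitness <- function(qcd) {
  qcd$z <- NA_real_
  lam <- list()
  for (sx in unique(qcd$sex)) {
    for (b in unique(qcd$block)) {
      i <- which(qcd$sex == sx & qcd$block == b)
      if (!length(i)) next
      r <- boxcox_scale_block(qcd$value[i])
      qcd$z[i] <- r$z
      lam[[paste(sx, b, sep = ".")]] <- r$lambda
    }
  }
  attr(qcd, "lambda") <- unlist(lam)
  qcd
}

#' Per-line, per-sex mean of normalised fitness
#'
#' Unweighted mean of surviving normalised observations across blocks.
#' Lines missing one sex entirely are flagged incomplete (NA mean for the
#' missing sex).
#'
#' @param normalised output of [normalise_fitness()].
#' @return data.frame: `line`, `mean_male`, `mean_female`, `complete`.
#' @export
line_means <- function(normalised) {
  lines <- sort(unique(normalised$line))
  mm <- tapply(normalised$z[normalised$sex == "M"],
               factor(normalised$line[normalised$sex == "M"], levels = lines),
               mean)
  mf <- tapply(normalised$z[normalised$sex == "F"],
               factor(normalised$line[normalised$sex == "F"], levels = lines),
               mean)
  out <- data.frame(line = lines, mean_male = as.numeric(mm),
                    mean_female = as.numeric(mf), stringsAsFactors = FALSE)
  out$complete <- !is.na(out$mean_male) & !is.na(out$mean_female)
  out
}

#' Rotate sex-specific fitness onto antagonism and concordant axes
#'
#' Multiplies each line's (male, female) mean-fitness coordinates by the
#' 45-degree rotation
#' \deqn{R = \begin{pmatrix} -1/\sqrt2 & -1/\sqrt2 \\ -1/\sqrt2 & 1/\sqrt2 \end{pmatrix}}
#' giving one sexually concordant and one sexually antagonistic axis. Sign
#' conventions: the antagonism index is positive for female-beneficial /
#' male-detrimental lines (`(f - m)/sqrt(2)`), and the concordant index is
#' negated so that higher values mean higher fitness in both sexes
#' (`(m + f)/sqrt(2)`). The rotation is an isometry, so
#' `a^2 + c^2 = m^2 + f^2` per line.
#'
#' @param means output of [line_means()] (incomplete lines get NA indices).
#' @return the input with `antagonism_index` and `concordant_index` added.
#' @export
rotate_indices <- function(means) {
  m <- means$mean_male
  f <- means$mean_female
  means$antagonism_index <- (f - m) / sqrt(2)
  means$concordant_index <- (m + f) / sqrt(2)
  means
}

#' Full fitness preprocessing chain
#'
#' [qc_vials()] then [normalise_fitness()] then [line_means()] then
#' [rotate_indices()]; incomplete lines are dropped from the result.
#'
#' @param raw assay table.
#' @return per-line data.frame with normalised sex means and both indices.
#' @export
fitness_pipeline <- function(raw) {
  lm_ <- rotate_indices(line_means(normalise_fitness(qc_vials(raw))))
  lm_[lm_$complete, , drop = FALSE]
}
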