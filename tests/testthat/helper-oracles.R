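# Independent brute-force oracles used to check the package implementations.
# These deliberately avoid the code paths they verify.

# Cohen's kappa straight from the 2x2 confusion table.
kappa_oracle <- function(observed, predicted) {
  tp <- sum(observed & predicted)
  fp <- sum(!observed & predicted)
  fn <- sum(observed & !predicted)
  tn <- sum(!observed & !predicted)
  n <- tp + fp + fn + tn
  po <- (tp + tn) / n
  pe <- ((tp + fn) * (tp + fp) + (tn + fp) * (tn + fn)) / n^2
  (po - pe) / (1 - pe)
}

# AUC by exhaustive concordant/discordant pair counting (ties count half).
auc_oracle <- function(observed, scores) {
  pos <- scores[observed]
  neg <- scores[!observed]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# Variance shares on a two-level factorial by explicit contrast sums:
# for a coded (+-1) orthogonal design replicated r times, the sum of squares
# of a term is (sum of y times the term's contrast)^2 / N.
anova_shares_oracle <- function(coded, responses) {
  if (is.matrix(responses)) {
    y <- as.vector(responses)
    X <- coded[rep(seq_len(nrow(coded)), times = ncol(responses)), ,
               drop = FALSE]
  } else {
    y <- responses
    X <- coded
  }
  N <- length(y)
  sst <- sum((y - mean(y))^2)
  k <- ncol(coded)
  main <- numeric(k)
  inter <- matrix(0, k, k)
  if (sst > 0) {
    for (j in seq_len(k)) main[j] <- sum(y * X[, j])^2 / N / sst
    for (a in seq_len(k - 1)) for (b in seq(a + 1, k))
      inter[a, b] <- inter[b, a] <- sum(y * X[, a] * X[, b])^2 / N / sst
  }
  list(main = main, interaction = inter)
}

# Minimal hand-built simulation result, for summary-statistic unit tests.
fake_result <- function(recruits, reproduction = recruits > 0,
                        latitudes = seq_len(ncol(recruits)),
                        spawner_ages = NULL) {
  years <- nrow(recruits)
  nb <- ncol(recruits)
  ids <- sprintf("b%02d", seq_len(nb))
  colnames(recruits) <- ids
  spage_w <- matrix(0, years, nb)
  spage_sum <- matrix(0, years, nb)
  if (!is.null(spawner_ages)) {
    spage_w[years, ] <- ifelse(is.na(spawner_ages), 0, 1)
    spage_sum[years, ] <- ifelse(is.na(spawner_ages), 0, spawner_ages)
  }
  structure(list(recruits = recruits, spawners = recruits,
                 reproduction = reproduction,
                 spawner_age_sum = spage_sum, spawner_age_weight = spage_w,
                 ticks = years * 4L, years = years,
                 basin_ids = ids, latitudes = latitudes,
                 config = list(seed = 0L, replicate_id = 0L)),
            class = "simulation_result")
}

# Tiny hand-made climate: every (basin, year, season) at the given
# temperatures (a named-by-season vector or a basins x 4 matrix).
flat_climate <- function(network, temps, years = 30, start_year = 1901) {
  ids <- network$basins$id
  if (is.null(dim(temps)))
    temps <- matrix(temps, nrow = length(ids), ncol = 4, byrow = TRUE,
                    dimnames = list(ids, c("winter", "spring", "summer",
                                           "fall")))
  grid <- expand.grid(basin_id = ids, year = start_year + seq_len(years) - 1,
                      season = c("winter", "spring", "summer", "fall"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$temperature <- temps[cbind(grid$basin_id, grid$season)]
  climate_series(grid, medium = "water")
}
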