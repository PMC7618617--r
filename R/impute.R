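#' k-nearest-neighbour imputation under Gower distance
#'
#' Fills missing covariate cells from the k nearest donor rows under the
#' Gower distance for mixed-type data: per variable, range-normalised
#' absolute difference for numerics and 0/1 mismatch for categoricals,
#' averaged over the variables observed in both rows. Continuous cells take
#' the donor median, categorical cells the donor mode. Observed cells are
#' never changed. Fat-mass-type outcome variables should not be passed in
#' (they are analysed complete-case, not imputed).
#'
#' @param data data.frame of covariates (factors/characters and numerics).
#' @param k donors per missing cell.
#' @param exclude column names left untouched and not used in the distance
#'   (e.g. ids, survey weights).
#' @return completed data.frame of the same shape.
#' @export
knn_impute <- function(data, k = 5L, exclude = c("participant_id", "survey_weight")) {
  was_dt <- data.table::is.data.table(data)
  data <- as.data.frame(data)
  vars <- setdiff(names(data), exclude)
  if (!length(vars)) return(data)
  sub <- data[vars]
  is_num <- vapply(sub, is.numeric, logical(1))
  for (v in vars[!is_num]) sub[[v]] <- as.character(sub[[v]])
  obs <- !is.na(as.matrix(sub))
  if (any(rowSums(obs) == 0L)) {
    stop("row(s) with every covariate missing cannot be imputed: ",
         paste(head(which(rowSums(obs) == 0L)), collapse = ", "))
  }
  frac_miss <- colMeans(!obs)
  if (any(frac_miss > 0.5)) {
    stop("covariate(s) with more than 50% missingness: ",
         paste(vars[frac_miss > 0.5], collapse = ", "))
  }
  rng <- vapply(sub[is_num], function(x) diff(range(x, na.rm = TRUE)), numeric(1))
  rng[rng == 0] <- 1
  num_mat <- as.matrix(as.data.frame(lapply(seq_along(sub)[is_num], function(j) {
    sub[[j]] / rng[[names(sub)[j]]]
  })))
  if (length(num_mat)) colnames(num_mat) <- vars[is_num]
  need <- which(rowSums(!obs) > 0L)
  out <- data
  for (i in need) {
    # componentwise Gower distance from row i to all rows, over variables
    # observed in both
    d_sum <- numeric(nrow(sub))
    d_cnt <- numeric(nrow(sub))
    for (j in seq_along(vars)) {
      v <- vars[j]
      if (is.na(sub[[v]][i])) next
      ok <- obs[, j]
      if (is_num[j]) {
        d <- abs(num_mat[, v] - num_mat[i, v])
      } else {
        d <- as.numeric(sub[[v]] != sub[[v]][i])
      }
      d_sum[ok] <- d_sum[ok] + d[ok]
      d_cnt[ok] <- d_cnt[ok] + 1
    }
    gower <- ifelse(d_cnt > 0, d_sum / d_cnt, Inf)
    gower[i] <- Inf
    for (j in which(is.na(sub[i, ]))) {
      donors <- which(obs[, j] & is.finite(gower))
      donors <- donors[order(gower[donors])][seq_len(min(k, length(donors)))]
      if (!length(donors)) next
      v <- vars[j]
      if (is_num[j]) {
        out[[v]][i] <- median(data[[v]][donors])
      } else {
        vals <- as.character(data[[v]][donors])
        out[[v]][i] <- names(sort(table(vals), decreasing = TRUE))[1L]
      }
    }
  }
  if (was_dt) data.table::as.data.table(out) else out
}
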