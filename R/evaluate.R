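# Regression and classification metrics, expert-to-movement mapping,
# confusion matrices, and center-segment relabeling.

#' Normalized root-mean-square error
#'
#' `sqrt(mean((y - y_hat)^2)) / (max(y) - min(y))`, per output column; the
#' range is taken from the reference signal `y`.
#'
#' @param y reference matrix or vector (N x d_y).
#' @param y_hat predictions of the same shape.
#' @return one NRMSE per column.
#' @export
#' @examples
#' nrmse(c(0, 1), c(0.5, 0.5)) # 0.5
nrmse <- function(y, y_hat) {
  y <- as_matrix(y, "y"); y_hat <- as_matrix(y_hat, "y_hat")
  stopifnot(all(dim(y) == dim(y_hat)))
  rng <- apply(y, 2L, function(col) diff(range(col)))
  if (any(rng == 0)) stop("reference signal has zero range in some DoF")
  sqrt(colMeans((y - y_hat)^2)) / rng
}

#' Coefficient of determination
#'
#' `1 - sum((y - y_hat)^2) / sum((y - mean(y))^2)` per output column; may go
#' negative when the residual sum exceeds the total sum of squares.
#'
#' @inheritParams nrmse
#' @return one R^2 per column.
#' @export
r2 <- function(y, y_hat) {
  y <- as_matrix(y, "y"); y_hat <- as_matrix(y_hat, "y_hat")
  stopifnot(all(dim(y) == dim(y_hat)))
  tss <- colSums(sweep(y, 2L, colMeans(y))^2)
  if (any(tss == 0)) stop("reference signal has zero variance in some DoF")
  1 - colSums((y - y_hat)^2) / tss
}

#' Map experts to movement labels by training-set majority vote
#'
#' The gating network clusters without supervision, so expert indices carry
#' no movement meaning. Each expert is mapped to the movement label it most
#' often wins on the training rows (ties to the lower movement id); experts
#' that win no rows map to rest (0).
#'
#' @param winners_train winning expert index per training row.
#' @param movements_train movement label per training row (0 = rest).
#' @param M number of experts (defaults to the largest winner index).
#' @return integer vector: movement id per expert.
#' @export
map_experts_to_movements <- function(winners_train, movements_train,
                                     M = max(winners_train)) {
  stopifnot(length(winners_train) == length(movements_train))
  mapping <- integer(M)
  for (i in seq_len(M)) {
    labs <- movements_train[winners_train == i]
    if (length(labs) == 0L) { mapping[i] <- 0L; next }
    tab <- table(labs)
    best <- tab == max(tab)
    mapping[i] <- min(as.integer(names(tab)[best]))
  }
  mapping
}

#' Classification accuracy
#'
#' Proportion of correctly classified instances, overall or per force
#' pattern (per true movement label).
#'
#' @param pred_movements predicted movement labels.
#' @param true_movements reference labels of the same length.
#' @param per_pattern if `TRUE`, return a named vector of accuracies per
#'   true label.
#' @export
classification_accuracy <- function(pred_movements, true_movements,
                                    per_pattern = FALSE) {
  if (length(pred_movements) == 0L) stop("empty input")
  stopifnot(length(pred_movements) == length(true_movements))
  if (!per_pattern) return(mean(pred_movements == true_movements))
  labs <- sort(unique(true_movements))
  vapply(setNames(labs, paste0("F", labs)), function(m) {
    idx <- true_movements == m
    mean(pred_movements[idx] == m)
  }, numeric(1))
}

#' Row-normalized confusion matrix
#'
#' Rows are true classes; entry (i, j) is the fraction of class-i instances
#' predicted as class j, so rows sum to 1 and perfect prediction gives the
#' identity.
#'
#' @inheritParams classification_accuracy
#' @param labels label set (defaults to the union of both sequences).
#' @export
confusion_matrix <- function(pred_movements, true_movements,
                             labels = sort(unique(c(pred_movements,
                                                    true_movements)))) {
  stopifnot(length(pred_movements) == length(true_movements))
  cm <- table(factor(true_movements, levels = labels),
              factor(pred_movements, levels = labels))
  cm <- unclass(cm / pmax(rowSums(cm), 1L))
  dimnames(cm) <- list(true = paste0("F", labels),
                       predicted = paste0("F", labels))
  cm
}

#' Center-segment mask for transition-robust scoring
#'
#' Divides every contiguous non-rest movement block into three segments of
#' equal size (the middle segment absorbing remainders) and keeps only the
#' center one; rest blocks are fully retained. Scoring only the plateau of
#' each movement removes the rest-to-movement transition windows that are
#' technically neither rest nor movement.
#'
#' @param movements per-row movement labels with contiguous blocks (0 =
#'   rest).
#' @return logical mask of rows to keep.
#' @export
#' @examples
#' center_segment_labels(rep(c(0, 1), c(4, 9))) # rest kept, middle 3 of 9
center_segment_labels <- function(movements) {
  n <- length(movements)
  if (n == 0L) return(logical(0))
  runs <- rle(movements)
  keep <- logical(n)
  pos <- 0L
  for (b in seq_along(runs$lengths)) {
    len <- runs$lengths[b]
    if (runs$values[b] == 0L) {
      keep[pos + seq_len(len)] <- TRUE
    } else {
      third <- len %/% 3L
      from <- pos + third + 1L
      to <- pos + len - third
      keep[from:to] <- TRUE
    }
    pos <- pos + len
  }
  keep
}

#' Evaluate a fitted model on a train/test pair
#'
#' Computes the full report: per-DoF NRMSE and R^2 on the test set,
#' per-pattern NRMSE, continuous and center-segment classification
#' accuracies (expert labels mapped to movements by training-set majority
#' vote), and the row-normalized confusion matrix.
#'
#' @param model a fitted [moe_fit()] object.
#' @param train,test [feature_dataset()]s on the model's feature scale.
#' @return a list of class `moe_report`.
#' @export
evaluate_model <- function(model, train, test) {
  stopifnot(inherits(model, "vbmoe"), inherits(train, "feature_dataset"),
            inherits(test, "feature_dataset"))
  mapping <- map_experts_to_movements(classify(model, train$X),
                                      train$movement, M = model$M)
  pred <- predict_sequence(model, test$X)
  pred_mov <- mapping[pred$winner]

  per_dof_nrmse <- nrmse(test$Y, pred$mean)
  per_dof_r2 <- r2(test$Y, pred$mean)
  pats <- sort(unique(test$movement[test$movement != 0L]))
  per_pattern_nrmse <- vapply(setNames(pats, paste0("F", pats)), function(m) {
    idx <- test$movement == m
    mean(nrmse(test$Y[idx, , drop = FALSE], pred$mean[idx, , drop = FALSE]))
  }, numeric(1))

  mask <- center_segment_labels(test$movement)
  structure(list(
    nrmse = per_dof_nrmse,
    r2 = per_dof_r2,
    mean_nrmse = mean(per_dof_nrmse),
    mean_r2 = mean(per_dof_r2),
    per_pattern_nrmse = per_pattern_nrmse,
    accuracy = classification_accuracy(pred_mov, test$movement),
    accuracy_per_pattern = classification_accuracy(pred_mov, test$movement,
                                                   per_pattern = TRUE),
    accuracy_segmented = classification_accuracy(pred_mov[mask],
                                                 test$movement[mask]),
    confusion = confusion_matrix(pred_mov, test$movement),
    expert_movement_map = mapping,
    n_test = nrow(test$X)), class = "moe_report")
}

#' @export
print.moe_report <- function(x, ...) {
  cat("Model evaluation on", x$n_test, "test rows\n")
  cat(sprintf("  mean NRMSE: %.2f%%   mean R^2: %.2f%%\n",
              100 * x$mean_nrmse, 100 * x$mean_r2))
  cat(sprintf("  accuracy: %.2f%% (continuous), %.2f%% (center segments)\n",
              100 * x$accuracy, 100 * x$accuracy_segmented))
  invisible(x)
}
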