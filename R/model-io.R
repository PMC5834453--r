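# Model serialization: human-inspectable JSON with an embedded schema
# version. Cholesky caches are recomputed on load, so the round trip
# reproduces predictions exactly.

MODEL_SCHEMA_VERSION <- 1L

enc_mat <- function(M) list(nrow = nrow(M), ncol = ncol(M),
                            data = as.numeric(t(M)))
dec_mat <- function(x) matrix(as.numeric(x$data), x$nrow, x$ncol, byrow = TRUE)
enc_mats <- function(lst) lapply(lst, enc_mat)
dec_mats <- function(lst) lapply(lst, dec_mat)

#' Save or load a fitted model
#'
#' Serializes every posterior parameter, the mixing weights, the
#' lower-bound trace and any attached standardizer to JSON at full numeric
#' precision. `load_model()` checks the embedded schema version and rebuilds
#' the factorization caches, so predictions from the loaded model match the
#' original.
#'
#' @param model a fitted [moe_fit()] object.
#' @param path file path of the JSON model file.
#' @return `save_model()` returns `path` invisibly; `load_model()` returns
#'   the `vbmoe` object.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "vbmoe"))
  h <- model$hyper
  obj <- list(
    schema_version = MODEL_SCHEMA_VERSION,
    generator = "vbmoe",
    M = model$M, d_x = model$d_x, d_y = model$d_y,
    N_train = model$N_train,
    pi = model$pi,
    gates = list(m = enc_mat(model$gates$m), beta = model$gates$beta,
                 nu = model$gates$nu, Nk = model$gates$Nk,
                 B = enc_mats(model$gates$B)),
    experts = list(W = enc_mats(model$experts$W),
                   L = enc_mats(model$experts$L),
                   lambda = model$experts$lambda,
                   Q = enc_mats(model$experts$Q),
                   Nk = model$experts$Nk),
    ard = list(c = model$ard$c, d = enc_mat(model$ard$d)),
    hyper = list(d_x = h$d_x, d_y = h$d_y, M_init = h$M_init,
                 beta0 = h$beta0, nu0 = h$nu0, lambda0 = h$lambda0,
                 c0 = h$c0, d0 = h$d0, B0 = enc_mat(h$B0),
                 Q0 = enc_mat(h$Q0), m0 = enc_mat(h$m0)),
    lower_bound_trace = model$lower_bound_trace,
    lower_bound = model$lower_bound,
    active_experts = model$active_experts,
    converged = model$converged,
    seed = model$seed,
    best_restart = model$best_restart,
    standardizer = if (is.null(model$standardizer)) NULL else
      list(mean = model$standardizer$mean, sd = model$standardizer$sd))
  # digits = I(17): bit-exact double round trip, so reloaded models predict
  # identically
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    stop("cannot parse model file: ", conditionMessage(e),
                         call. = FALSE))
  if (is.null(obj$schema_version) ||
      obj$schema_version != MODEL_SCHEMA_VERSION)
    stop("model schema version mismatch: expected ", MODEL_SCHEMA_VERSION,
         ", found ", obj$schema_version %||% "none")

  h <- obj$hyper
  hyper <- moe_hyper(h$d_x, h$d_y, M_init = h$M_init, beta0 = h$beta0,
                     B0 = dec_mat(as.list(h$B0)), nu0 = h$nu0,
                     Q0 = dec_mat(as.list(h$Q0)), lambda0 = h$lambda0,
                     c0 = h$c0, d0 = h$d0)
  hyper$m0 <- dec_mat(as.list(h$m0))

  dec_list <- function(x) {
    # read_json(simplifyVector=TRUE) yields a data.frame-ish list of rows
    if (is.data.frame(x)) lapply(seq_len(nrow(x)), function(i)
      dec_mat(list(nrow = x$nrow[i], ncol = x$ncol[i], data = x$data[[i]])))
    else lapply(x, dec_mat)
  }

  B <- dec_list(obj$gates$B)
  gates <- list(m = dec_mat(as.list(obj$gates$m)), beta = obj$gates$beta,
                nu = obj$gates$nu, Nk = obj$gates$Nk, B = B,
                cholB = lapply(B, chol_jitter, what = "gate scale B"),
                logdetB = vapply(B, function(Bi)
                  logdet_from_chol(chol_jitter(Bi, "B")), numeric(1)))

  L <- dec_list(obj$experts$L)
  Q <- dec_list(obj$experts$Q)
  cholC <- lapply(L, function(Li)
    chol_jitter(chol2inv(chol_jitter(Li, "L")), "design precision"))
  experts <- list(W = dec_list(obj$experts$W), L = L,
                  cholC = cholC,
                  lambda = obj$experts$lambda, Q = Q,
                  cholQ = lapply(Q, chol_jitter, what = "Q"),
                  Nk = obj$experts$Nk,
                  logdetL = vapply(L, function(Li)
                    logdet_from_chol(chol_jitter(Li, "L")), numeric(1)),
                  logdetQ = vapply(Q, function(Qi)
                    logdet_from_chol(chol_jitter(Qi, "Q")), numeric(1)))

  ard_d <- dec_mat(as.list(obj$ard$d))
  standardizer <- NULL
  if (!is.null(obj$standardizer))
    standardizer <- structure(list(mean = obj$standardizer$mean,
                                   sd = obj$standardizer$sd),
                              class = "standardizer")

  structure(list(
    pi = obj$pi, gates = gates, experts = experts,
    ard = list(c = obj$ard$c, d = ard_d, Upsilon = obj$ard$c / ard_d),
    r = NULL, hyper = hyper,
    lower_bound_trace = obj$lower_bound_trace,
    lower_bound = obj$lower_bound,
    active_experts = obj$active_experts,
    M = obj$M, d_x = obj$d_x, d_y = obj$d_y, N_train = obj$N_train,
    converged = obj$converged, seed = obj$seed,
    restart_seeds = NULL, best_restart = obj$best_restart,
    standardizer = standardizer),
    class = "vbmoe")
}
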