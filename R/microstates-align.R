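# Group-level template alignment: full-permutation class matching with
# polarity ignored, iterated mean templates, and the run -> participant ->
# condition -> global aggregation hierarchy.

# All permutations of 1..k as a k! x k integer matrix.
.permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(k - 1L)
  out <- matrix(0L, k * nrow(sub), k)
  row <- 1L
  for (i in seq_len(k)) {
    rest <- seq_len(k)[-i]
    for (j in seq_len(nrow(sub))) {
      out[row, ] <- c(i, rest[sub[j, ]])
      row <- row + 1L
    }
  }
  out
}

# Best class permutation of model templates `tpl` against `ref` by maximal
# sum of absolute spatial correlations; returns list(perm, signs, score).
.best_permutation <- function(ref, tpl, perms) {
  C <- abs(stats::cor(ref, tpl))            # K x K, rows = ref classes
  K <- ncol(C)
  idx <- cbind(rep(seq_len(K), times = nrow(perms)), as.vector(t(perms)))
  scores <- rowSums(matrix(C[idx], ncol = K, byrow = TRUE))
  best <- which.max(scores)
  perm <- perms[best, ]
  signs <- vapply(seq_len(K), function(k) {
    r <- stats::cor(ref[, k], tpl[, perm[k]])
    if (r < 0) -1 else 1
  }, numeric(1))
  list(perm = perm, signs = signs, score = scores[best])
}

#' Align microstate models and average their templates
#'
#' Builds a mean model from models with a common number of classes: for each
#' input model all `K!` class permutations are scored by the sum of absolute
#' spatial correlations (Pearson, across channels) with the current mean
#' templates; the best permutation is applied, each aligned template's sign
#' is flipped to make its correlation with the mean positive (polarity is
#' ignored throughout), templates are averaged and re-normalized, and the
#' procedure repeats until the assignments are stable.
#'
#' @param models List of `microstate_model`s sharing `K` and channel count.
#' @param perm_cap Hard cap on `K!` (default `factorial(10)`); larger K is an
#'   error, as full permutation becomes intractable.
#' @param max_passes Iteration cap on the realignment loop.
#' @return A `microstate_model` holding the mean templates (unit norm, zero
#'   channel mean); `$alignment` records each model's permutation and signs.
#' @export
align_and_average <- function(models, perm_cap = factorial(10), max_passes = 20L) {
  stopifnot(length(models) >= 1L)
  K <- models[[1]]$K
  if (!all(vapply(models, `[[`, integer(1), "K") == K))
    stop("all models must share the same number of classes")
  if (factorial(K) > perm_cap)
    stop("K! = ", factorial(K), " permutations exceed the cap (", perm_cap,
         "); lower K or raise perm_cap")
  if (length(models) == 1L) {
    out <- models[[1]]
    out$alignment <- list(list(perm = seq_len(K), signs = rep(1, K)))
    return(out)
  }
  perms <- .permutations(K)
  mean_tpl <- models[[1]]$templates
  prev_perms <- NULL
  alignment <- NULL
  for (pass in seq_len(max_passes)) {
    aligned <- vector("list", length(models))
    alignment <- vector("list", length(models))
    for (m in seq_along(models)) {
      b <- .best_permutation(mean_tpl, models[[m]]$templates, perms)
      aligned[[m]] <- sweep(models[[m]]$templates[, b$perm, drop = FALSE],
                            2L, b$signs, "*")
      alignment[[m]] <- b[c("perm", "signs")]
    }
    mean_tpl <- unit_norm(avg_ref_cols(
      Reduce(`+`, aligned) / length(aligned)))
    cur <- lapply(alignment, `[[`, "perm")
    if (!is.null(prev_perms) && identical(cur, prev_perms)) break
    prev_perms <- cur
  }
  structure(list(templates = mean_tpl, K = K, F = NA_real_, cv = NA_real_,
                 assign = NULL, a = NULL, gev = NA_real_,
                 n_maps = sum(vapply(models, `[[`, integer(1), "n_maps")),
                 level = "mean", labels = NULL, alignment = alignment),
            class = "microstate_model")
}

#' Aggregate run-level microstate models up the study hierarchy
#'
#' Mean classes are computed across runs (one model per participant and
#' condition), then across participants (one model per condition), then
#' across conditions (the global model), each step via [align_and_average()].
#' Missing cells are skipped with a warning.
#'
#' @param models List of run-level `microstate_model`s.
#' @param index Data frame aligned with `models`: columns `participant`,
#'   `condition`, `run`.
#' @return List with `participant_condition` (named list
#'   `"p<P>/<condition>"`), `condition` (named list), and `global` (one
#'   `microstate_model`), each model's `level` field set accordingly.
#' @export
aggregate_hierarchy <- function(models, index) {
  stopifnot(length(models) == nrow(index))
  pc <- list()
  for (p in unique(index$participant)) {
    for (cond in unique(index$condition[index$participant == p])) {
      sel <- which(index$participant == p & index$condition == cond)
      if (length(sel) == 0L) {
        warning("missing cell: participant ", p, ", ", cond)
        next
      }
      m <- align_and_average(models[sel])
      m$level <- "participant_condition"
      pc[[sprintf("p%d/%s", p, cond)]] <- m
    }
  }
  cond_models <- list()
  for (cond in unique(index$condition)) {
    sel <- grep(paste0("/", cond, "$"), names(pc))
    if (length(sel) == 0L) {
      warning("no participant models for condition ", cond)
      next
    }
    m <- align_and_average(pc[sel])
    m$level <- "condition"
    cond_models[[cond]] <- m
  }
  global <- align_and_average(cond_models)
  global$level <- "global"
  list(participant_condition = pc, condition = cond_models, global = global)
}

#' Assign class letters by correlation with a reference template set
#'
#' Classes are lettered by maximal absolute spatial correlation with a
#' packaged reference set (a synthetic six-map stand-in stored at
#' `inst/extdata/canonical_templates_synthetic.csv`), using the same
#' full-permutation matching as model alignment when the class counts agree,
#' and greedy unique matching otherwise.
#'
#' @param model A `microstate_model`.
#' @param reference channels x m reference matrix with lettered column names
#'   (default: the packaged synthetic set).
#' @return The model with `$labels` set.
#' @export
assign_class_letters <- function(model, reference = NULL) {
  if (is.null(reference)) {
    path <- system.file("extdata", "canonical_templates_synthetic.csv",
                        package = "eegms")
    ref_df <- utils::read.csv(path, stringsAsFactors = FALSE)
    reference <- as.matrix(ref_df[, -1L])
    rownames(reference) <- ref_df[[1L]]
  }
  K <- model$K
  letters_ref <- colnames(reference)
  if (K == ncol(reference) && factorial(K) <= factorial(8)) {
    b <- .best_permutation(model$templates, reference, .permutations(K))
    model$labels <- letters_ref[b$perm]
  } else {
    C <- abs(stats::cor(model$templates, reference))
    lab <- rep(NA_character_, K)
    for (i in seq_len(min(K, ncol(reference)))) {
      pos <- which(C == max(C), arr.ind = TRUE)[1, ]
      lab[pos[1]] <- letters_ref[pos[2]]
      C[pos[1], ] <- -Inf
      C[, pos[2]] <- -Inf
    }
    lab[is.na(lab)] <- paste0("X", which(is.na(lab)))
    model$labels <- lab
  }
  model
}
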