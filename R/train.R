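#' Training configuration and scenario presets
#'
#' Four built-in presets cover the transfer scenarios; they differ only in
#' the loss weights `alpha` (contrastive), `beta` (feature alignment),
#' `gamma` (sparse center), the temperature `tau`, and the iteration cap
#' (3000 for cross-modality transfers, 200 within one modality).
#'
#' @param scenario one of `"matched_rna_atac"`, `"unmatched_rna_atac"`,
#'   `"rna_to_rna"`, `"atac_to_atac"`.
#' @return a `scenario_config` (see [scenario_config]) carrying the preset
#'   weights and iteration cap.
#' @export
scenario_preset <- function(scenario) {
  presets <- list(
    matched_rna_atac   = list(alpha = 0.06, beta = 0.05, gamma = 0.01,
                              tau = 0.04, max_iterations = 3000L),
    unmatched_rna_atac = list(alpha = 1.2, beta = 0.05, gamma = 0.01,
                              tau = 0.8, max_iterations = 3000L),
    rna_to_rna         = list(alpha = 0.1, beta = 0, gamma = 0.1,
                              tau = 0.8, max_iterations = 200L),
    atac_to_atac       = list(alpha = 0.1, beta = 0, gamma = 0.001,
                              tau = 0.8, max_iterations = 200L)
  )
  if (!scenario %in% names(presets)) {
    stop_data("unknown scenario '", scenario, "'; available: ",
              paste(names(presets), collapse = ", "))
  }
  ps <- presets[[scenario]]
  scenario_config(scenario = scenario, alpha = ps$alpha, beta = ps$beta,
                  gamma = ps$gamma, tau = ps$tau,
                  max_iterations = ps$max_iterations)
}

#' @rdname scenario_preset
#' @param alpha,beta,gamma loss weights (contrastive, alignment, sparse
#'   center); the cross-entropy weight is 1 and the projection-regularizer
#'   weight is fixed at 0.1.
#' @param tau contrastive temperature (> 0).
#' @param p_frac feature-alignment top fraction in (0, 1].
#' @param batch_size mini-batch size per side (default 512).
#' @param learning_rate initial SGD learning rate (default 0.001).
#' @param momentum SGD momentum (default 0.9).
#' @param max_iterations iteration cap.
#' @param patience consecutive flat sparse-loss iterations before early
#'   stop (default 20).
#' @param sc_tolerance plateau tolerance `|delta L_SC|` (default 1e-4).
#' @param warmup iterations before pseudo-labeled query cells join the
#'   sparse center loss and center updates (default 100).
#' @param confidence_threshold open-set rejection threshold in (0, 1).
#' @param hidden_dims,m,e_dim architecture (see [model_config]).
#' @param knn_k,n_components neighbor-graph parameters (see
#'   [build_knn_graph]).
#' @param center_update_rate class-center step size in (0, 1].
#' @param seed integer seed governing initialization and sampling.
#' @export
scenario_config <- function(scenario = "custom", alpha = 0.1, beta = 0,
                            gamma = 0.1, tau = 0.8, p_frac = 0.2,
                            batch_size = 512L, learning_rate = 0.001,
                            momentum = 0.9, max_iterations = 200L,
                            patience = 20L, sc_tolerance = 1e-4,
                            warmup = 100L, confidence_threshold = 0.95,
                            hidden_dims = 1024L, m = 64L, e_dim = 32L,
                            knn_k = 15L, n_components = 50L,
                            center_update_rate = 0.5, seed = 1L) {
  if (tau <= 0) stop_data("tau must be positive")
  if (confidence_threshold <= 0 || confidence_threshold >= 1) {
    stop_data("confidence_threshold must lie in (0, 1)")
  }
  if (max_iterations < 1L) stop_data("max_iterations must be >= 1")
  structure(list(scenario = scenario, alpha = alpha, beta = beta,
                 gamma = gamma, tau = tau, p_frac = p_frac,
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, momentum = momentum,
                 max_iterations = as.integer(max_iterations),
                 patience = as.integer(patience), sc_tolerance = sc_tolerance,
                 warmup = as.integer(warmup),
                 confidence_threshold = confidence_threshold,
                 hidden_dims = as.integer(hidden_dims), m = as.integer(m),
                 e_dim = as.integer(e_dim), knn_k = as.integer(knn_k),
                 n_components = as.integer(n_components),
                 center_update_rate = center_update_rate,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

# epoch-wise sampler: permutes indices, draws without replacement, and
# reshuffles (recycles) when exhausted, so batches from both sides always
# have equal size
make_sampler <- function(n) {
  s <- new.env(parent = emptyenv())
  s$n <- n
  s$perm <- sample.int(n)
  s$pos <- 0L
  s
}

draw_batch <- function(s, size) {
  out <- integer(0)
  while (length(out) < size) {
    take <- min(size - length(out), s$n - s$pos)
    if (take > 0L) {
      out <- c(out, s$perm[(s$pos + 1L):(s$pos + take)])
      s$pos <- s$pos + take
    }
    if (s$pos >= s$n) {
      s$perm <- sample.int(s$n)
      s$pos <- 0L
    }
  }
  out
}

#' Sample equal-size reference/query mini-batches
#'
#' Exposed for testing; [fit_annotator] drives the same samplers
#' internally. Within an epoch each cell appears at most once; the smaller
#' side recycles with a fresh shuffle.
#'
#' @param sampler_r,sampler_q sampler states from the internal constructor.
#' @param batch_size cells per side.
#' @return list with integer vectors `batch_r`, `batch_q`.
#' @keywords internal
sample_minibatches <- function(sampler_r, sampler_q, batch_size) {
  list(batch_r = draw_batch(sampler_r, batch_size),
       batch_q = draw_batch(sampler_q, batch_size))
}

# Builds the joint objective on a fresh tape: shared forward pass over
# [reference batch; query batch; sampled positives], the five losses, and
# their weighted total. `sc_labels` pairs with `sc_rows` (row indices into
# the concatenated batch). Returns everything train_step (and the gradient
# checker) needs.
training_objective <- function(model, config, Xr_batch, y_batch, Xq_batch,
                               Xpos_batch, centers, sc_query_labels = NULL) {
  nr <- nrow(Xr_batch); nb <- nrow(Xq_batch)
  X <- rbind(Xr_batch, Xq_batch, Xpos_batch)
  tape <- ad_tape()
  leaves <- ad_param_leaves(tape, model$params)
  Xnode <- ad_leaf(tape, X)
  fw <- nn_embed_train(tape, leaves, model$config, Xnode)
  Dall <- fw$d
  idx_r <- seq_len(nr)
  idx_q <- nr + seq_len(nb)
  Dr <- ad_gather_rows(tape, Dall, idx_r)
  Dq <- ad_gather_rows(tape, Dall, idx_q)
  Dp <- ad_gather_rows(tape, Dall, nr + nb + seq_len(nrow(Xpos_batch)))

  logits_r <- nn_logits(tape, leaves, Dr)
  l_ce <- ad_ce_loss_logits(tape, logits_r, y_batch)
  l_pr <- ad_pr_loss(tape, Dq, Dr)
  l_cl <- ad_cl_loss(tape, Dq, Dp, config$tau)
  l_fa <- ad_fa_loss(tape, Dq, Dr, config$p_frac)
  logits_q <- nn_logits(tape, leaves, Dq)

  if (!is.null(sc_query_labels)) {
    sc_rows <- c(idx_r, idx_q)
    sc_labels <- c(y_batch, sc_query_labels)
  } else {
    sc_rows <- idx_r
    sc_labels <- y_batch
  }
  Dsc <- ad_gather_rows(tape, Dall, sc_rows)
  att <- nn_attention_train(tape, leaves, Dsc)
  l_sc <- ad_sc_loss(tape, Dsc, att$a, centers, sc_labels)

  total <- ad_add(tape, l_ce, ad_scale(tape, l_pr, 0.1))
  if (config$alpha != 0) total <- ad_add(tape, total, ad_scale(tape, l_cl, config$alpha))
  if (config$beta != 0) total <- ad_add(tape, total, ad_scale(tape, l_fa, config$beta))
  if (config$gamma != 0) total <- ad_add(tape, total, ad_scale(tape, l_sc, config$gamma))

  list(tape = tape, leaves = leaves, total = total,
       parts = total_loss(l_ce$value[1L], l_pr$value[1L], l_cl$value[1L],
                          l_fa$value[1L], l_sc$value[1L],
                          config$alpha, config$beta, config$gamma),
       Dall = Dall, logits_q = logits_q, fw = fw, att = att,
       sc_rows = sc_rows, sc_labels = sc_labels)
}

# one optimization step; everything numeric in/out. `data` carries Xr, y_r
# (integer labels), Xq; `state` is the mutable train state environment.
train_step <- function(model, opt, data, graph, config, state,
                       batch_r, batch_q) {
  positives <- sample_positives(graph, batch_q)
  y_batch <- data$y_r[batch_r]

  use_query_sc <- state$iteration > config$warmup &&
    !anyNA(state$pseudo_labels[batch_q])
  obj <- training_objective(model, config,
                            data$Xr[batch_r, , drop = FALSE], y_batch,
                            data$Xq[batch_q, , drop = FALSE],
                            data$Xq[positives, , drop = FALSE],
                            state$centers,
                            sc_query_labels = if (use_query_sc)
                              state$pseudo_labels[batch_q] else NULL)
  tape <- obj$tape

  # pseudo-labels for the query batch from the current classifier
  pq <- softmax_rows(obj$logits_q$value)
  state$pseudo_labels[batch_q] <- max.col(pq, ties.method = "first")
  state$pseudo_confidence[batch_q] <- apply(pq, 1L, max)

  parts <- obj$parts
  if (!is.finite(parts$total)) {
    bad <- names(which(!vapply(parts[c("l_ce", "l_pr", "l_cl", "l_fa", "l_sc")],
                               is.finite, logical(1))))
    stop_data("non-finite training loss at iteration ", state$iteration,
              " (diverged term: ",
              if (length(bad)) paste(bad, collapse = ", ") else "total",
              ")")
  }

  ad_backward(tape, obj$total)
  for (nm in names(model$params)) {
    g <- ad_grad(obj$leaves[[nm]])
    opt[[nm]] <- config$momentum * opt[[nm]] - config$learning_rate * g
    model$params[[nm]] <- model$params[[nm]] + opt[[nm]]
  }
  model <- update_running_stats(model, obj$fw$bn_stats, obj$att$bn_stats)

  # dynamic centers follow the (pre-update) batch embeddings
  d_sc_val <- obj$Dall$value[obj$sc_rows, , drop = FALSE]
  state$centers <- update_centers(state$centers, d_sc_val, obj$sc_labels,
                                  config$center_update_rate)

  list(model = model, opt = opt, breakdown = parts)
}

#' Fit the semi-supervised label-transfer model
#'
#' Runs the joint training loop: equal-size reference/query mini-batches
#' pass through the shared extractor; the five losses are combined per the
#' configured weights; parameters take one SGD-with-momentum step; class
#' centers and pseudo-labels are refreshed every iteration. Training stops
#' at `max_iterations`, or earlier once the sparse center loss changes by
#' less than `sc_tolerance` for `patience` consecutive iterations (the
#' plateau rule is disabled when `gamma = 0`, where the sparse loss does
#' not influence the objective).
#'
#' Inputs must already be on a common feature space and log-normalized
#' (see [intersect_features], [log_normalize]); the neighbor graph is built
#' from the query with [build_knn_graph] when not supplied.
#'
#' @param ref labeled [expression_matrix] (reference).
#' @param query unlabeled [expression_matrix] (query), same features.
#' @param config a [scenario_config] or the name of a preset.
#' @param graph optional precomputed `neighbor_graph` of the query.
#' @return list of class `lb_fit`: `model` (trained `lb_model` with
#'   `classes` and `feature_names` set), `state` (final centers,
#'   pseudo-labels, iteration count), `log` (per-iteration loss breakdown
#'   data.frame).
#' @export
fit_annotator <- function(ref, query, config, graph = NULL) {
  if (is.character(config)) config <- scenario_preset(config)
  stopifnot(inherits(config, "scenario_config"))
  if (is.null(ref$labels)) stop_data("reference must carry cell type labels")
  if (!identical(ref$feature_names, query$feature_names)) {
    stop_data("reference and query feature spaces differ; run intersect_features first")
  }
  classes <- sort(unique(ref$labels))
  if (length(classes) < 2L) stop_data("need at least 2 reference cell types")
  y_r <- match(ref$labels, classes)

  with_seed(config$seed, {
    if (is.null(graph)) {
      graph <- build_knn_graph(query, n_components = config$n_components,
                               k = config$knn_k, normalize = FALSE)
    }
    mcfg <- model_config(input_dim = n_features(ref), K = length(classes),
                         hidden_dims = config$hidden_dims, m = config$m,
                         e_dim = config$e_dim)
    model <- init_model(mcfg, seed = config$seed)
    opt <- lapply(model$params, function(v) array(0, dim(v)))

    state <- new.env(parent = emptyenv())
    state$iteration <- 0L
    state$centers <- init_centers(length(classes), config$m)
    state$pseudo_labels <- rep(NA_integer_, n_cells(query))
    state$pseudo_confidence <- rep(NA_real_, n_cells(query))
    state$sc_history <- numeric(0)

    sampler_r <- make_sampler(n_cells(ref))
    sampler_q <- make_sampler(n_cells(query))
    data <- list(Xr = ref$values, y_r = y_r, Xq = query$values)

    log_rows <- vector("list", config$max_iterations)
    flat <- 0L
    last_sc <- NA_real_
    for (it in seq_len(config$max_iterations)) {
      state$iteration <- it
      b <- sample_minibatches(sampler_r, sampler_q, config$batch_size)
      step <- train_step(model, opt, data, graph, config, state,
                         b$batch_r, b$batch_q)
      model <- step$model
      opt <- step$opt
      bd <- step$breakdown
      log_rows[[it]] <- data.frame(iteration = it, l_ce = bd$l_ce,
                                   l_pr = bd$l_pr, l_cl = bd$l_cl,
                                   l_fa = bd$l_fa, l_sc = bd$l_sc,
                                   total = bd$total)
      state$sc_history <- utils::tail(c(state$sc_history, bd$l_sc),
                                      config$patience + 1L)
      if (isTRUE(getOption("labelbridge.verbose")) && it %% 100L == 0L) {
        message(sprintf(
          "iter %d: ce=%.4f pr=%.4f cl=%.4f fa=%.4f sc=%.4f total=%.4f",
          it, bd$l_ce, bd$l_pr, bd$l_cl, bd$l_fa, bd$l_sc, bd$total))
      }
      if (config$gamma > 0) {
        if (!is.na(last_sc) && abs(bd$l_sc - last_sc) < config$sc_tolerance) {
          flat <- flat + 1L
        } else {
          flat <- 0L
        }
        last_sc <- bd$l_sc
        if (flat >= config$patience) break
      }
    }
    model$classes <- classes
    model$feature_names <- ref$feature_names
    structure(list(model = model, state = state,
                   log = do.call(rbind, log_rows[!vapply(log_rows, is.null,
                                                         logical(1))])),
              class = "lb_fit")
  })
}

#' Current pseudo-labels of the query cells
#'
#' Pseudo-labels are the classifier's running predictions for query cells,
#' refreshed for each mini-batch as training proceeds; cells not yet
#' visited are `NA`.
#'
#' @param fit an `lb_fit` from [fit_annotator], or a train-state
#'   environment.
#' @return data.frame with `pseudo_label` (class name) and `confidence`.
#' @export
pseudo_labels <- function(fit) {
  state <- if (inherits(fit, "lb_fit")) fit$state else fit
  classes <- if (inherits(fit, "lb_fit")) fit$model$classes else NULL
  lab <- state$pseudo_labels
  data.frame(
    pseudo_label = if (is.null(classes)) lab else classes[lab],
    confidence = state$pseudo_confidence,
    stringsAsFactors = FALSE
  )
}
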