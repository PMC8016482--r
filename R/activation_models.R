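# Spreading-activation memory-network models of generalization reaction times.
#
# Four networks share the same dynamics: every node's activation starts at 0
# and, on each trial, grows toward an asymptote of 1 by a Rescorla-Wagner step
# a <- a + r * (1 - a), where the per-trial rate r of a node depends on its
# relation to the probed condition. Direct retrieval runs at rate alpha1,
# mediated retrieval at alpha2 per intervening step, and incidental retrieval
# of task-irrelevant nodes at alpha3; multi-step paths multiply their rates
# (power-law fall-off). The predicted raw RT of a trial is the maximum joint
# asymptotic activation of the probed read-out nodes minus their current
# (pre-update) activation, so retrieval is slow when the probed nodes are
# weakly activated.

MODEL_KINDS <- c("CAR", "IAR", "LS", "HLS")

#' Activation rate parameters
#'
#' @param alpha1 direct-retrieval rate in [0, 1].
#' @param alpha2 mediated-retrieval rate in [0, 1].
#' @param alpha3 incidental-retrieval rate in [0, 1].
#' @return named numeric vector of class `activation_params`.
#' @export
activation_params <- function(alpha1, alpha2, alpha3) {
  p <- c(alpha1 = alpha1, alpha2 = alpha2, alpha3 = alpha3)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("rate parameters must lie in [0, 1]")
  structure(p, class = "activation_params")
}

as_params <- function(p) {
  if (inherits(p, "activation_params")) return(unclass(p))
  p <- unlist(p, use.names = FALSE)
  stopifnot(length(p) == 3L)
  unclass(activation_params(p[1], p[2], p[3]))
}

# ---- node inventories -------------------------------------------------------

node_id <- function(type, a, b = NULL) {
  if (is.null(b)) paste(type, a, sep = "|") else paste(type, a, b, sep = "|")
}

node_inventory <- function(model_kind, design) {
  d <- design
  switch(model_kind,
    CAR = {
      init <- expand.grid(context = d$contexts$context,
                          category = d$old_categories,
                          stringsAsFactors = FALSE)
      init$origin <- "initial"
      newt <- expand.grid(context = unname(d$trained_contexts),
                          category = d$new_categories,
                          stringsAsFactors = FALSE)
      newt$origin <- "new"
      gen <- expand.grid(context = d$heldout_contexts,
                         category = d$new_categories,
                         stringsAsFactors = FALSE)
      gen$origin <- "gen"
      nodes <- rbind(init, newt, gen)
      nodes$type <- "conj"
      nodes$latent_state <- context_ls(d, nodes$context)
      nodes$value <- condition_value(d, nodes$context, nodes$category)
      nodes$id <- node_id("conj", nodes$context, nodes$category)
      nodes
    },
    IAR = {
      ctx <- data.frame(type = "ctx", context = d$contexts$context,
                        category = NA, origin = NA,
                        latent_state = d$contexts$latent_state,
                        value = NA, stringsAsFactors = FALSE)
      ctx$id <- node_id("ctx", ctx$context)
      cv <- unique(data.frame(
        category = rep(colnames(d$value_map), each = 3L),
        value = as.integer(d$value_map),
        stringsAsFactors = FALSE))
      cv <- data.frame(type = "catval", context = NA, category = cv$category,
                       origin = NA, latent_state = NA, value = cv$value,
                       stringsAsFactors = FALSE)
      cv$id <- node_id("catval", cv$category, ifelse(cv$value > 0, "+", "-"))
      rbind(ctx, cv)
    },
    LS = {
      ls <- data.frame(type = "ls", context = NA, category = NA, origin = NA,
                       latent_state = d$latent_states, value = NA,
                       stringsAsFactors = FALSE)
      ls$id <- node_id("ls", ls$latent_state)
      lc <- expand.grid(latent_state = d$latent_states,
                        category = colnames(d$value_map),
                        stringsAsFactors = FALSE)
      lc <- data.frame(type = "lscat", context = NA, category = lc$category,
                       origin = NA, latent_state = lc$latent_state,
                       value = d$value_map[cbind(lc$latent_state, lc$category)],
                       stringsAsFactors = FALSE)
      lc$id <- node_id("lscat", lc$latent_state, lc$category)
      rbind(ls, lc)
    },
    HLS = {
      ls <- data.frame(type = "ls", context = NA, category = NA, origin = NA,
                       latent_state = d$latent_states, value = NA,
                       stringsAsFactors = FALSE)
      ls$id <- node_id("ls", ls$latent_state)
      ctx <- data.frame(type = "ctx", context = d$contexts$context,
                        category = NA, origin = NA,
                        latent_state = d$contexts$latent_state, value = NA,
                        stringsAsFactors = FALSE)
      ctx$id <- node_id("ctx", ctx$context)
      cc <- expand.grid(context = d$contexts$context,
                        category = colnames(d$value_map),
                        stringsAsFactors = FALSE)
      cc <- data.frame(type = "ctxcat", context = cc$context,
                       category = cc$category, origin = NA,
                       latent_state = context_ls(d, cc$context),
                       value = condition_value(d, cc$context, cc$category),
                       stringsAsFactors = FALSE)
      cc$id <- node_id("ctxcat", cc$context, cc$category)
      rbind(ls, ctx, cc)
    },
    stop("unknown model kind: ", model_kind)
  )
}

#' Build a memory network
#'
#' Constructs the model-specific node inventory with all activations
#' initialized at zero. CAR holds one node per context-category conjunction
#' (27 initial-training, 9 new-training, 18 generalization); IAR holds 9
#' context nodes plus the experienced category-value nodes; LS holds 3
#' latent-state nodes plus latent-state-by-category nodes; HLS holds 3
#' latent-state, 9 context, and context-by-category nodes, with contexts
#' nested under their latent state.
#'
#' @param model_kind one of `"CAR"`, `"IAR"`, `"LS"`, `"HLS"`.
#' @param design a `task_design`.
#' @return an object of class `memory_network`.
#' @export
build_network <- function(model_kind, design) {
  model_kind <- match.arg(model_kind, MODEL_KINDS)
  nodes <- node_inventory(model_kind, design)
  rownames(nodes) <- NULL
  structure(list(
    model_kind = model_kind,
    design = design,
    nodes = nodes,
    activation = stats::setNames(rep(0, nrow(nodes)), nodes$id)
  ), class = "memory_network")
}

#' @export
print.memory_network <- function(x, ...) {
  cat(x$model_kind, "memory network:", nrow(x$nodes), "nodes (",
      paste(names(table(x$nodes$type)), table(x$nodes$type), collapse = ", "),
      ")\n")
  invisible(x)
}

#' Rescorla-Wagner activation update
#'
#' One saturating learning step toward the asymptote 1:
#' `a + rate * (1 - a)`.
#'
#' @param activation current activation level(s) in [0, 1].
#' @param rate learning rate(s) in [0, 1].
#' @return updated activation level(s).
#' @export
rw_update <- function(activation, rate) {
  if (any(activation < 0 | activation > 1) || any(rate < 0 | rate > 1))
    stop("activation and rate must lie in [0, 1]")
  activation + rate * (1 - activation)
}

# ---- relation classes and their rates --------------------------------------

# per-model relation classes; order matters only for documentation, every node
# gets exactly one class
model_classes <- function(model_kind) {
  switch(model_kind,
    CAR = c("other", "same_value_other_initial", "linked_trained_new",
            "current_ctx_initial", "newtrain_same_category",
            "current_conjunction", "sibling_conjunction"),
    IAR = c("other", "sibling_context", "other_new_catvals",
            "initial_catvals", "trained_context", "current_catval",
            "current_context"),
    LS  = c("other_ls", "other_ls_categories", "other_categories_current_ls",
            "current_ls_category", "current_ls"),
    HLS = c("other_ls", "other_ls_contexts", "other_ls_categories",
            "same_ls_other_contexts", "same_ls_nested_categories",
            "current_context_category", "current_context", "current_ls")
  )
}

# monomial rate of each relation class in (alpha1, alpha2, alpha3)
class_rates <- function(model_kind, params) {
  p <- as_params(params)
  a1 <- p[[1]]; a2 <- p[[2]]; a3 <- p[[3]]
  r <- switch(model_kind,
    CAR = c(a3, a2, a2^2, a1, a1, a1^2 * a2^2, a1^2 * a2^3),
    IAR = c(a3, a1^2 * a2, a1^3 * a2, a1^2, a1^3, a1^4, a1),
    LS  = c(a3, a3^2, a2, a1^2, a1),
    HLS = c(a3, a3^2, a3^3, a1 * a2, a1 * a2^2, a1^3, a1^2, a1)
  )
  stats::setNames(r, model_classes(model_kind))
}

# integer relation class of every node for a probe of (context, category);
# assignments later in the sequence overwrite earlier ones, so the most
# specific (most direct) relation wins where textual pathways overlap
classify_nodes <- function(model_kind, design, nodes, context, category) {
  cls_names <- model_classes(model_kind)
  cls <- rep(1L, nrow(nodes))  # default: incidental ("other")
  L <- context_ls(design, context)
  set <- function(mask, name) {
    cls[mask & !is.na(mask)] <<- match(name, cls_names)
  }
  if (model_kind == "CAR") {
    trained <- linked_trained_context(design, context)
    sib <- sibling_heldout_context(design, context)
    cur_vals <- design$value_map[L, ]
    set(nodes$origin == "initial" & nodes$context != context &
          nodes$value == cur_vals[nodes$category],
        "same_value_other_initial")
    set(nodes$origin == "new" & nodes$context == trained,
        "linked_trained_new")
    set(nodes$origin == "initial" & nodes$context == context,
        "current_ctx_initial")
    set(nodes$origin == "new" & nodes$category == category,
        "newtrain_same_category")
    set(nodes$origin == "gen" & nodes$context == context &
          nodes$category == category, "current_conjunction")
    set(nodes$origin == "gen" & nodes$context == sib &
          nodes$category == category, "sibling_conjunction")
  } else if (model_kind == "IAR") {
    trained <- linked_trained_context(design, context)
    sib <- sibling_heldout_context(design, context)
    v <- condition_value(design, context, category)
    set(nodes$type == "ctx" & nodes$context == sib, "sibling_context")
    new_cv <- design$value_map[L, design$new_categories]
    set(nodes$type == "catval" & nodes$category %in% design$new_categories &
          nodes$category != category &
          nodes$value == new_cv[nodes$category], "other_new_catvals")
    old_cv <- design$value_map[L, design$old_categories]
    set(nodes$type == "catval" & nodes$category %in% design$old_categories &
          nodes$value == old_cv[nodes$category], "initial_catvals")
    set(nodes$type == "ctx" & nodes$context == trained, "trained_context")
    set(nodes$type == "catval" & nodes$category == category &
          nodes$value == v, "current_catval")
    set(nodes$type == "ctx" & nodes$context == context, "current_context")
  } else if (model_kind == "LS") {
    set(nodes$type == "lscat" & nodes$latent_state != L, "other_ls_categories")
    set(nodes$type == "lscat" & nodes$latent_state == L &
          nodes$category != category, "other_categories_current_ls")
    set(nodes$type == "lscat" & nodes$latent_state == L &
          nodes$category == category, "current_ls_category")
    set(nodes$type == "ls" & nodes$latent_state == L, "current_ls")
    # non-current LS nodes keep the default class, renamed for clarity
    cls[nodes$type == "ls" & nodes$latent_state != L] <-
      match("other_ls", cls_names)
  } else { # HLS
    set(nodes$type == "ctx" & nodes$latent_state != L, "other_ls_contexts")
    set(nodes$type == "ctxcat" & nodes$latent_state != L,
        "other_ls_categories")
    set(nodes$type == "ctx" & nodes$latent_state == L &
          nodes$context != context, "same_ls_other_contexts")
    set(nodes$type == "ctxcat" & nodes$latent_state == L &
          !(nodes$context == context & nodes$category == category),
        "same_ls_nested_categories")
    set(nodes$type == "ctxcat" & nodes$context == context &
          nodes$category == category, "current_context_category")
    set(nodes$type == "ctx" & nodes$context == context, "current_context")
    set(nodes$type == "ls" & nodes$latent_state == L, "current_ls")
  }
  cls
}

#' Per-node retrieval rates for one trial
#'
#' Classifies every node of the network by its relation to the probed
#' condition and returns the corresponding rate (a monomial in alpha1, alpha2,
#' alpha3) for each node.
#'
#' @param network a `memory_network`.
#' @param trial a trial record (list or one-row data frame with `context` and
#'   `category` from a generalization phase).
#' @param params `activation_params` or a length-3 numeric vector.
#' @return named numeric vector of rates, one per node.
#' @export
classify_and_rate <- function(network, trial, params) {
  context <- as.character(trial$context)
  category <- as.character(trial$category)
  if (!category %in% network$design$new_categories)
    stop("trial condition not representable: generalization trials probe new categories")
  cls <- classify_nodes(network$model_kind, network$design, network$nodes,
                        context, category)
  rates <- class_rates(network$model_kind, params)[cls]
  names(rates) <- network$nodes$id
  rates
}

# read-out node ids (length 1 for CAR, else 2) and the asymptotic constant
readout_nodes <- function(model_kind, design, context, category) {
  switch(model_kind,
    CAR = list(ids = node_id("conj", context, category), const = 1),
    IAR = {
      v <- condition_value(design, context, category)
      list(ids = c(node_id("ctx", context),
                   node_id("catval", category, if (v > 0) "+" else "-")),
           const = 2)
    },
    LS = {
      L <- context_ls(design, context)
      list(ids = c(node_id("ls", L), node_id("lscat", L, category)), const = 2)
    },
    HLS = list(ids = c(node_id("ctx", context),
                       node_id("ctxcat", context, category)), const = 2)
  )
}

#' Advance the network by one trial
#'
#' Reads out the predicted raw RT from the pre-update activation state
#' (asymptotic maximum of the probed nodes minus their current activation) and
#' then applies the Rescorla-Wagner update to every node at its classified
#' rate, all nodes updating simultaneously from the pre-trial state.
#'
#' @inheritParams classify_and_rate
#' @return list with `rt` (raw predicted RT) and the updated `network`.
#' @export
step_trial <- function(network, trial, params) {
  ro <- readout_nodes(network$model_kind, network$design,
                      as.character(trial$context), as.character(trial$category))
  rt <- ro$const - sum(network$activation[ro$ids])
  rates <- classify_and_rate(network, trial, params)
  network$activation <- rw_update(network$activation, rates)
  list(rt = rt, network = network)
}

# ---- fast product-form engine ----------------------------------------------

# Because 1 - a_T(n) = prod_t (1 - r_t(n)), the pre-trial activation of any
# node is determined by the counts of each relation class it occupied on
# earlier trials. This precomputes, for each trial's read-out nodes, those
# class counts, so predictions for new parameter values cost two small
# matrix-vector products.
precompute_prediction <- function(model_kind, design, sequence) {
  model_kind <- match.arg(model_kind, MODEL_KINDS)
  nodes <- node_inventory(model_kind, design)
  n_t <- nrow(sequence)
  n_n <- nrow(nodes)
  cls_names <- model_classes(model_kind)
  K <- length(cls_names)

  conds <- unique(sequence[, c("context", "category")])
  cls_by_cond <- matrix(0L, nrow(conds), n_n)
  ro_by_cond <- vector("list", nrow(conds))
  node_pos <- stats::setNames(seq_len(n_n), nodes$id)
  for (i in seq_len(nrow(conds))) {
    cls_by_cond[i, ] <- classify_nodes(model_kind, design, nodes,
                                       conds$context[i], conds$category[i])
    ro <- readout_nodes(model_kind, design, conds$context[i], conds$category[i])
    ro_by_cond[[i]] <- list(idx = unname(node_pos[ro$ids]), const = ro$const)
  }
  cond_of_trial <- match(paste(sequence$context, sequence$category),
                         paste(conds$context, conds$category))
  cls <- cls_by_cond[cond_of_trial, , drop = FALSE]  # trials x nodes

  # class counts over trials u < t for each trial's read-out nodes
  ro1 <- vapply(cond_of_trial, function(i) ro_by_cond[[i]]$idx[1], 0L)
  two <- length(ro_by_cond[[1]]$idx) == 2L
  ro2 <- if (two) vapply(cond_of_trial, function(i) ro_by_cond[[i]]$idx[2], 0L)
  M1 <- matrix(0, n_t, K)
  M2 <- if (two) matrix(0, n_t, K)
  for (k in seq_len(K)) {
    ind <- cls == k
    cum <- apply(ind, 2, cumsum)
    before <- rbind(0, cum[-n_t, , drop = FALSE])
    M1[, k] <- before[cbind(seq_len(n_t), ro1)]
    if (two) M2[, k] <- before[cbind(seq_len(n_t), ro2)]
  }
  list(model_kind = model_kind, M1 = M1, M2 = M2,
       const = ro_by_cond[[1]]$const, n_trials = n_t)
}

predict_raw_from_precompute <- function(pre, params) {
  rho <- pmin(class_rates(pre$model_kind, params), 1 - 1e-12)
  l1m <- log1p(-rho)
  a1 <- 1 - exp(drop(pre$M1 %*% l1m))
  a2 <- if (is.null(pre$M2)) 0 else 1 - exp(drop(pre$M2 %*% l1m))
  pre$const - a1 - a2
}

# generalization trials eligible for RT modeling: correct responses only (when
# behavior is populated)
modelable_trials <- function(sequence) {
  keep <- grepl("^generalization", sequence$phase)
  if (!is.null(sequence$correct) && any(!is.na(sequence$correct)))
    keep <- keep & !is.na(sequence$correct) & sequence$correct
  sequence[keep, , drop = FALSE]
}

#' Predicted standardized RTs for a trial sequence
#'
#' Runs a freshly initialized network of the given kind over the (correct)
#' generalization trials of `sequence` and returns the raw predicted RTs
#' z-scored across trials. The default engine uses a closed-form product
#' representation of the Rescorla-Wagner recursion; `engine = "step"` runs the
#' explicit trial-by-trial update (identical results, used for verification).
#'
#' @param model_kind one of `"CAR"`, `"IAR"`, `"LS"`, `"HLS"`.
#' @param params `activation_params` or length-3 numeric.
#' @param sequence a `trial_sequence` (or data frame with `phase`, `context`,
#'   `category`, optionally `correct`) with a `task_design` attribute, or pass
#'   `design` explicitly.
#' @param design `task_design`; defaults to `design_of(sequence)`.
#' @param engine `"product"` (fast closed form) or `"step"`.
#' @return z-scored predicted RT vector with attributes `raw` (raw RTs) and,
#'   when the raw predictions are constant, `degenerate = TRUE` (zeros
#'   returned).
#' @export
predict_sequence <- function(model_kind, params, sequence,
                             design = design_of(sequence),
                             engine = c("product", "step")) {
  engine <- match.arg(engine)
  if (is.null(design)) stop("no task_design attached to sequence; pass `design`")
  trials <- modelable_trials(sequence)
  if (nrow(trials) < 2L) stop("need at least 2 generalization trials")
  raw <- if (engine == "product") {
    pre <- precompute_prediction(model_kind, design, trials)
    predict_raw_from_precompute(pre, params)
  } else {
    net <- build_network(model_kind, design)
    out <- numeric(nrow(trials))
    for (t in seq_len(nrow(trials))) {
      st <- step_trial(net, trials[t, ], params)
      out[t] <- st$rt
      net <- st$network
    }
    out
  }
  z <- zscore(raw)
  attr(z, "raw") <- raw
  z
}
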