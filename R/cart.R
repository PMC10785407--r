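#' CART configuration
#'
#' @param learning_fraction fraction of subjects in the learning set
#'   (default 0.65; the remainder is the testing set).
#' @param min_node_size minimum subjects in a child node; a node is only
#'   split when it holds at least `2 * min_node_size` subjects.
#' @param min_split_gain minimum impurity gain for a split to be taken.
#' @param max_depth maximum tree depth (root = 0).
#' @param cv_folds cross-validation folds for pruning (>= 2; `n` gives
#'   leave-one-out).
#' @param impurity `"information"` (entropy in bits, the information
#'   index) or `"gini"`.
#' @param cutpoints optional named list restricting numeric split
#'   thresholds to fixed clinical cutpoints, e.g.
#'   `list(age = 45, cne = 95)`; variables not listed keep the free
#'   midpoint search.
#' @param one_se use the 1-SE rule when choosing the pruned subtree
#'   (the smallest subtree within one standard error of the minimal
#'   cross-validated error); default `FALSE`, i.e. the subtree with the
#'   minimal cross-validated error (ties prefer the smaller subtree).
#' @param cv_metric held-out error used to select the subtree:
#'   `"deviance"` (default; binomial log-loss, the cross-validated
#'   counterpart of the information index) or `"misclassification"`.
#' @param seed seed controlling the learning/testing split and CV folds.
#' @return A list of class `CartConfig`.
#' @export
cartConfig <- function(learning_fraction = 0.65, min_node_size = 20,
                       min_split_gain = 0, max_depth = 6, cv_folds = 10,
                       impurity = c("information", "gini"),
                       cutpoints = NULL, one_se = FALSE,
                       cv_metric = c("deviance", "misclassification"),
                       seed = 1) {
  impurity <- match.arg(impurity)
  cv_metric <- match.arg(cv_metric)
  assertScalarNumber(learning_fraction, "learning_fraction", 1e-9, 1 - 1e-9)
  if (cv_folds < 2) stop("'cv_folds' must be >= 2")
  structure(list(learning_fraction = learning_fraction,
                 min_node_size = as.integer(min_node_size),
                 min_split_gain = min_split_gain,
                 max_depth = as.integer(max_depth),
                 cv_folds = as.integer(cv_folds), impurity = impurity,
                 cutpoints = cutpoints, one_se = one_se,
                 cv_metric = cv_metric, seed = as.integer(seed)),
            class = "CartConfig")
}

#' Binary entropy of a case/control node, in bits
#'
#' `-sum(p * log2(p))` over the two classes, with `0 * log(0) = 0`; 0 for
#' a pure node, 1 bit for a 50/50 node.
#'
#' @param n_case,n_ctrl class counts (positive total).
#' @return Entropy in bits.
#' @examples
#' nodeEntropy(25, 25)  # 1
#' nodeEntropy(30, 10)  # 0.8113
#' @export
nodeEntropy <- function(n_case, n_ctrl) {
  n <- n_case + n_ctrl
  if (any(n <= 0)) stop("empty node has no entropy")
  p <- n_case / n
  plogp <- function(x) ifelse(x <= 0, 0, x * log2(x))
  -(plogp(p) + plogp(1 - p))
}

# Gini impurity (config alternative to the information index)
nodeGini <- function(n_case, n_ctrl) {
  n <- n_case + n_ctrl
  if (any(n <= 0)) stop("empty node has no impurity")
  p <- n_case / n
  2 * p * (1 - p)
}

.impurityFun <- function(impurity) {
  if (impurity == "gini") nodeGini else nodeEntropy
}

#' Stratified learning/testing partition
#'
#' Randomly splits subjects into a learning set (`learning_fraction`,
#' default 65%) and a testing set, stratified by case/control status so
#' each stratum hits the target fraction within one subject.
#'
#' @param status case/control vector.
#' @param learning_fraction learning-set fraction.
#' @param seed seed making the split reproducible.
#' @return List with integer index vectors `learning` and `testing`.
#' @export
partitionLearningTesting <- function(status, learning_fraction = 0.65,
                                     seed = 1) {
  status <- as.character(status)
  withSeed(seed, {
    learning <- integer(0)
    for (s in unique(status)) {
      idx <- which(status == s)
      k <- round(learning_fraction * length(idx))
      learning <- c(learning, sort(sample(idx, k)))
    }
    learning <- sort(learning)
    list(learning = learning,
         testing = setdiff(seq_along(status), learning))
  })
}

#' Candidate binary splits of one predictor
#'
#' Enumerates the binary partitions examined for a variable: a factor
#' with k levels yields the `2^(k-1) - 1` level-subset bipartitions (for
#' the 3-level genotype factor: `{AA}` vs `{AB,BB}`, `{BB}` vs `{AA,AB}`,
#' `{AB}` vs `{AA,BB}`); a logical yields one split; an ordered numeric
#' yields thresholds at the midpoints of its sorted unique values, or the
#' configured fixed cutpoints when given.  A constant variable yields no
#' splits.
#'
#' @param x predictor vector (factor, logical or numeric).
#' @param cutpoints optional numeric cutpoints for a numeric `x`.
#' @return List of split descriptors: `list(type = "cat", left = levels)`
#'   or `list(type = "num", threshold = t)` (left child is `x < t`).
#' @export
candidateSplits <- function(x, cutpoints = NULL) {
  if (is.logical(x)) x <- factor(x, levels = c("FALSE", "TRUE"))
  if (is.character(x)) x <- factor(x)
  if (is.factor(x)) {
    lev <- levels(x)[tabulate(x, length(levels(x))) > 0]
    if (length(lev) < 2) return(list())
    # subsets containing the first observed level, never the full set
    subsets <- list()
    others <- lev[-1]
    for (size in 0:(length(others) - 1)) {
      if (size == 0) {
        subsets[[length(subsets) + 1L]] <- lev[1]
      } else {
        comb <- utils::combn(others, size, simplify = FALSE)
        for (cs in comb)
          subsets[[length(subsets) + 1L]] <- c(lev[1], cs)
      }
    }
    return(lapply(subsets, function(s) list(type = "cat", left = s)))
  }
  if (is.numeric(x)) {
    u <- sort(unique(x))
    if (length(u) < 2) return(list())
    thr <- if (!is.null(cutpoints)) {
      ct <- sort(unique(cutpoints))
      ct[ct > u[1] & ct <= u[length(u)]]
    } else {
      (u[-1] + u[-length(u)]) / 2
    }
    return(lapply(thr, function(t) list(type = "num", threshold = t)))
  }
  stop("unsupported predictor type: ", class(x)[1])
}

.applySplit <- function(x, split) {
  if (split$type == "cat") {
    if (is.logical(x)) x <- factor(x, levels = c("FALSE", "TRUE"))
    out <- as.character(x) %in% split$left
    out[is.na(x)] <- NA
    out
  } else {
    x < split$threshold
  }
}

#' Best binary split of a node
#'
#' Scans every variable (in declaration order) and every candidate
#' partition (in enumeration order) and returns the split maximizing the
#' impurity gain: parent impurity minus the child-size-weighted mean
#' child impurity.  Splits leaving a child below `min_node_size` are
#' skipped; ties keep the first candidate encountered, so the result is
#' deterministic.  Returns `NULL` when no admissible split has gain above
#' `min_split_gain`.
#'
#' @param data `data.frame` of predictors.
#' @param y logical/0-1 case indicator.
#' @param config a [cartConfig()].
#' @return `list(variable, split, gain)` or `NULL`.
#' @export
bestSplit <- function(data, y, config = cartConfig()) {
  y <- as.logical(y)
  n <- length(y)
  if (n < 2 * config$min_node_size) return(NULL)
  imp <- .impurityFun(config$impurity)
  n_case <- sum(y)
  parent <- imp(n_case, n - n_case)
  if (parent == 0) return(NULL)
  best <- NULL
  best_gain <- max(config$min_split_gain, 0)
  for (v in colnames(data)) {
    x <- data[[v]]
    if (is.numeric(x) && is.null(config$cutpoints[[v]])) {
      cand <- .bestNumericSplit(x, y, imp, parent, config$min_node_size)
      if (!is.null(cand) && cand$gain > best_gain + 1e-12) {
        best <- list(variable = v,
                     split = list(type = "num", threshold = cand$threshold),
                     gain = cand$gain)
        best_gain <- cand$gain
      }
      next
    }
    for (split in candidateSplits(x, config$cutpoints[[v]])) {
      left <- .applySplit(x, split)
      nl <- sum(left); nr <- n - nl
      if (nl < config$min_node_size || nr < config$min_node_size) next
      cl <- sum(y[left]); cr <- n_case - cl
      child <- (nl * imp(cl, nl - cl) + nr * imp(cr, nr - cr)) / n
      gain <- parent - child
      if (gain > best_gain + 1e-12) {
        best <- list(variable = v, split = split, gain = gain)
        best_gain <- gain
      }
    }
  }
  best
}

# vectorized scan over all midpoint thresholds of a numeric predictor
.bestNumericSplit <- function(x, y, imp, parent, min_node_size) {
  ord <- order(x)
  xs <- x[ord]; ys <- y[ord]
  n <- length(xs)
  cum_case <- cumsum(ys)
  # positions after which the value changes: admissible cut positions
  pos <- which(diff(xs) > 0)
  pos <- pos[pos >= min_node_size & (n - pos) >= min_node_size]
  if (!length(pos)) return(NULL)
  nl <- pos
  cl <- cum_case[pos]
  nr <- n - nl
  cr <- cum_case[n] - cl
  child <- (nl * imp(cl, nl - cl) + nr * imp(cr, nr - cr)) / n
  gain <- parent - child
  i <- which.max(gain)  # first maximum -> smallest threshold on ties
  if (gain[i] <= 0) return(NULL)
  list(threshold = (xs[pos[i]] + xs[pos[i] + 1]) / 2, gain = gain[i])
}

#' CartTree: a fitted classification tree
#'
#' S4 container for a binary classification tree over case/control data.
#' Nodes are stored in preorder as a list of records (id, depth, counts,
#' impurity, split descriptor, child ids, terminal flag).
#'
#' @slot nodes list of node records.
#' @slot variables character vector of predictor names.
#' @slot config the [cartConfig()] used.
#' @slot n_learning learning-set size.
#' @export
setClass("CartTree", representation(nodes = "list", variables = "character",
                                    config = "list",
                                    n_learning = "integer"))

setValidity("CartTree", function(object) {
  for (nd in object@nodes) {
    if (!nd$terminal && is.null(nd$removed)) {
      l <- object@nodes[[nd$left_id]]; r <- object@nodes[[nd$right_id]]
      if (l$n_case + r$n_case != nd$n_case ||
          l$n_ctrl + r$n_ctrl != nd$n_ctrl)
        return("children's counts do not sum to parent's")
    }
  }
  TRUE
})

#' Grow a classification tree by recursive partitioning
#'
#' Recursively applies [bestSplit()] until a node is pure, too small,
#' too deep, or no split has positive gain.  Node ids are assigned in
#' deterministic preorder (left subtree before right).
#'
#' @param data `data.frame` of predictors (complete cases).
#' @param y logical/0-1 case indicator.
#' @param config a [cartConfig()].
#' @return A [CartTree-class].
#' @export
growTree <- function(data, y, config = cartConfig()) {
  y <- as.logical(y)
  stopifnot(nrow(data) == length(y), nrow(data) > 0)
  if (anyNA(data))
    stop("growTree requires complete predictor data; drop or impute NAs first")
  imp <- .impurityFun(config$impurity)
  env <- new.env()
  env$nodes <- list()
  build <- function(idx, depth) {
    id <- length(env$nodes) + 1L
    n_case <- sum(y[idx]); n_ctrl <- length(idx) - n_case
    node <- list(id = id, depth = depth, n_case = n_case, n_ctrl = n_ctrl,
                 impurity = imp(n_case, n_ctrl), terminal = TRUE,
                 variable = NA_character_, split = NULL, gain = NA_real_,
                 left_id = NA_integer_, right_id = NA_integer_)
    env$nodes[[id]] <- node
    if (depth < config$max_depth) {
      found <- bestSplit(data[idx, , drop = FALSE], y[idx], config)
      if (!is.null(found)) {
        left <- .applySplit(data[idx, , drop = FALSE][[found$variable]],
                            found$split)
        node$terminal <- FALSE
        node$variable <- found$variable
        node$split <- found$split
        node$gain <- found$gain
        env$nodes[[id]] <- node
        node$left_id <- build(idx[left], depth + 1L)
        node$right_id <- build(idx[!left], depth + 1L)
        env$nodes[[id]] <- node
      }
    }
    id
  }
  build(seq_along(y), 0L)
  new("CartTree", nodes = env$nodes, variables = colnames(data),
      config = unclass(config), n_learning = length(y))
}

#' @describeIn growTree number of terminal nodes of a tree.
#' @param tree a [CartTree-class].
#' @export
nTerminalNodes <- function(tree) {
  sum(vapply(tree@nodes, `[[`, logical(1), "terminal"))
}

setMethod("show", "CartTree", function(object) {
  cat(sprintf("CartTree: %d nodes (%d terminal), %d learning subjects\n",
              length(object@nodes), nTerminalNodes(object),
              object@n_learning))
  render <- function(id, indent) {
    nd <- object@nodes[[id]]
    lab <- if (nd$terminal) "*" else
      sprintf("%s %s", nd$variable, .splitLabel(nd$split, TRUE))
    cat(sprintf("%snode %d [%d case/%d ctrl] %s\n", indent, nd$id,
                nd$n_case, nd$n_ctrl, lab))
    if (!nd$terminal) {
      render(nd$left_id, paste0(indent, "  "))
      render(nd$right_id, paste0(indent, "  "))
    }
  }
  render(1L, "")
  invisible(NULL)
})

.splitLabel <- function(split, left) {
  if (split$type == "num") {
    if (left) sprintf("< %g", split$threshold)
    else sprintf(">= %g", split$threshold)
  } else {
    if (left) sprintf("in {%s}", paste(split$left, collapse = ","))
    else sprintf("not in {%s}", paste(split$left, collapse = ","))
  }
}

#' Route subjects to terminal nodes
#'
#' @param tree a [CartTree-class].
#' @param data predictor `data.frame` with the tree's variables.
#' @return Integer vector of terminal node ids; `NA` for subjects with a
#'   missing value on a split variable (unroutable).
#' @export
routeSubjects <- function(tree, data) {
  out <- rep(NA_integer_, nrow(data))
  recurse <- function(id, idx) {
    nd <- tree@nodes[[id]]
    if (nd$terminal) {
      out[idx] <<- id
      return(invisible(NULL))
    }
    x <- data[[nd$variable]][idx]
    left <- .applySplit(x, nd$split)
    ok <- !is.na(left)
    recurse(nd$left_id, idx[ok & left])
    recurse(nd$right_id, idx[ok & !left])
  }
  if (nrow(data)) recurse(1L, seq_len(nrow(data)))
  out
}

# majority-class prediction per node (tie -> control)
.nodePrediction <- function(tree) {
  vapply(tree@nodes, function(nd) nd$n_case > nd$n_ctrl, logical(1))
}

# misclassification count of the routed data under the tree
.misclassification <- function(tree, data, y) {
  leaf <- routeSubjects(tree, data)
  pred <- .nodePrediction(tree)[leaf]
  sum(pred != as.logical(y), na.rm = TRUE) + sum(is.na(leaf))
}

# held-out binomial deviance (log-loss) with Laplace-smoothed leaf rates
.heldOutDeviance <- function(tree, data, y) {
  leaf <- routeSubjects(tree, data)
  p_leaf <- vapply(tree@nodes, function(nd)
    (nd$n_case + 0.5) / (nd$n_case + nd$n_ctrl + 1), numeric(1))
  p <- p_leaf[leaf]
  y <- as.logical(y)
  -2 * sum(ifelse(y, log(p), log1p(-p)), na.rm = TRUE)
}

.heldOutError <- function(tree, data, y, metric) {
  if (metric == "deviance") .heldOutDeviance(tree, data, y)
  else .misclassification(tree, data, y)
}

# ---- cost-complexity pruning ------------------------------------------

# leaf risk R(T_t) (misclassification count) and leaf count per node
.subtreeStats <- function(tree) {
  n <- length(tree@nodes)
  R_leaf <- numeric(n); leaves <- integer(n)
  walk <- function(id) {
    nd <- tree@nodes[[id]]
    if (nd$terminal) {
      R_leaf[id] <<- min(nd$n_case, nd$n_ctrl)
      leaves[id] <<- 1L
    } else {
      walk(nd$left_id); walk(nd$right_id)
      R_leaf[id] <<- R_leaf[nd$left_id] + R_leaf[nd$right_id]
      leaves[id] <<- leaves[nd$left_id] + leaves[nd$right_id]
    }
  }
  walk(1L)
  list(R_leaf = R_leaf, leaves = leaves)
}

#' Prune a tree at complexity parameter alpha
#'
#' Collapses, iteratively, every internal node whose weakest-link value
#' `g(t) = (R(t) - R(T_t)) / (|leaves(T_t)| - 1)` (misclassification
#' counts on the learning set) is `<= alpha`.
#'
#' @param tree a [CartTree-class].
#' @param alpha complexity parameter (>= 0).
#' @return The pruned [CartTree-class] (node ids unchanged; descendants
#'   of collapsed nodes removed).
#' @export
pruneAtAlpha <- function(tree, alpha) {
  repeat {
    st <- .subtreeStats(tree)
    internal <- which(vapply(tree@nodes, function(nd)
      !nd$terminal && is.null(nd$removed), logical(1)))
    if (!length(internal)) return(tree)
    g <- vapply(internal, function(id) {
      nd <- tree@nodes[[id]]
      (min(nd$n_case, nd$n_ctrl) - st$R_leaf[id]) /
        max(st$leaves[id] - 1L, 1L)
    }, numeric(1))
    gmin <- min(g)
    if (gmin > alpha + 1e-12) return(tree)
    for (id in internal[g <= gmin + 1e-12])
      tree <- .collapseNode(tree, id)
  }
}

.collapseNode <- function(tree, id) {
  drop <- integer(0)
  gather <- function(i) {
    if (is.na(i)) return(invisible(NULL))
    nd <- tree@nodes[[i]]
    if (!isTRUE(nd$removed) && !nd$terminal) {
      drop <<- c(drop, nd$left_id, nd$right_id)
      gather(nd$left_id); gather(nd$right_id)
    }
  }
  nd <- tree@nodes[[id]]
  if (isTRUE(nd$removed) || nd$terminal) return(tree)
  gather(id)
  nd$terminal <- TRUE
  nd$variable <- NA_character_; nd$split <- NULL; nd$gain <- NA_real_
  nd$left_id <- NA_integer_; nd$right_id <- NA_integer_
  tree@nodes[[id]] <- nd
  # replace removed descendants with tombstones so ids stay stable
  tree@nodes[drop] <- lapply(drop, function(i)
    list(id = i, depth = NA_integer_, n_case = 0L, n_ctrl = 0L,
         impurity = NA_real_, terminal = FALSE, removed = TRUE,
         variable = NA_character_, split = NULL, gain = NA_real_,
         left_id = NA_integer_, right_id = NA_integer_))
  tree
}

# alphas of the weakest-link pruning sequence of a tree
.ccAlphas <- function(tree) {
  alphas <- 0
  t <- tree
  repeat {
    internal <- which(vapply(t@nodes, function(nd)
      !nd$terminal && is.null(nd$removed), logical(1)))
    if (!length(internal)) break
    st <- .subtreeStats(t)
    g <- vapply(internal, function(id) {
      nd <- t@nodes[[id]]
      (min(nd$n_case, nd$n_ctrl) - st$R_leaf[id]) /
        max(st$leaves[id] - 1L, 1L)
    }, numeric(1))
    gmin <- max(min(g), 0)
    alphas <- c(alphas, gmin)
    t <- pruneAtAlpha(t, gmin)
  }
  sort(unique(alphas))
}

#' Cross-validation-guided cost-complexity pruning
#'
#' Computes the weakest-link pruning sequence of the fitted tree, then
#' estimates each candidate subtree's misclassification error by k-fold
#' cross-validation (stratified folds; a tree is regrown on each fold's
#' training part and pruned at the geometric-mean alpha), and returns the
#' subtree with the lowest cross-validated error.  Ties prefer the
#' smaller subtree; the optional 1-SE rule picks the smallest subtree
#' within one standard error of the minimum.  Deterministic given
#' `config$seed`.
#'
#' @param tree a [CartTree-class] grown on `data`/`y`.
#' @param data,y the learning data the tree was grown on.
#' @param config a [cartConfig()] (`cv_folds`, `one_se`, `seed`).
#' @return List with `tree` (pruned [CartTree-class]), `cv`
#'   (`data.frame`: alpha, size, cv error count) and `alpha` chosen.
#' @export
cvPrune <- function(tree, data, y, config = cartConfig()) {
  y <- as.logical(y)
  n <- length(y)
  alphas <- .ccAlphas(tree)
  if (length(alphas) == 1)
    return(list(tree = tree, alpha = 0,
                cv = data.frame(alpha = 0, size = nTerminalNodes(tree),
                                cv_error = NA_real_)))
  betas <- c(sqrt(alphas[-length(alphas)] * alphas[-1]), Inf)
  folds <- if (config$cv_folds >= n) {
    seq_len(n)  # leave-one-out
  } else {
    withSeed(config$seed, {
      f <- integer(n)
      for (cls in unique(y)) {
        idx <- which(y == cls)
        f[idx] <- sample(rep_len(seq_len(config$cv_folds), length(idx)))
      }
      f
    })
  }
  metric <- if (is.null(config$cv_metric)) "deviance" else config$cv_metric
  fold_ids <- sort(unique(folds))
  cv_mat <- matrix(0, nrow = length(fold_ids), ncol = length(betas))
  for (ki in seq_along(fold_ids)) {
    train <- folds != fold_ids[ki]
    ft <- growTree(data[train, , drop = FALSE], y[train], config)
    for (j in seq_along(betas)) {
      pt <- pruneAtAlpha(ft, betas[j])
      cv_mat[ki, j] <- .heldOutError(pt, data[!train, , drop = FALSE],
                                     y[!train], metric)
    }
  }
  cv_err <- colSums(cv_mat)
  jmin <- max(which(cv_err == min(cv_err)))
  pick <- if (config$one_se) {
    # SE of the CV total from the between-fold spread
    se <- stats::sd(cv_mat[, jmin]) * sqrt(nrow(cv_mat))
    if (!is.finite(se)) se <- 0
    max(which(cv_err <= min(cv_err) + se))
  } else {
    jmin  # ties -> larger alpha, smaller tree
  }
  pruned <- pruneAtAlpha(tree, betas[pick])
  sizes <- vapply(betas, function(b) nTerminalNodes(pruneAtAlpha(tree, b)),
                  numeric(1))
  list(tree = pruned, alpha = betas[pick],
       cv = data.frame(alpha = betas, size = sizes, cv_error = cv_err))
}

# human-readable predicate conjunction for each terminal node
.nodePredicates <- function(tree) {
  preds <- character(length(tree@nodes))
  walk <- function(id, path) {
    nd <- tree@nodes[[id]]
    preds[id] <<- if (length(path)) paste(path, collapse = " & ") else "(all)"
    if (!nd$terminal) {
      walk(nd$left_id, c(path, paste(nd$variable,
                                     .splitLabel(nd$split, TRUE))))
      walk(nd$right_id, c(path, paste(nd$variable,
                                      .splitLabel(nd$split, FALSE))))
    }
  }
  walk(1L, character(0))
  preds
}

#' Terminal-node risk table
#'
#' Routes the evaluation subjects down the tree, takes the terminal node
#' with the lowest case fraction as the reference (ties -> larger node,
#' then smaller id), and estimates each node's crude odds ratio against
#' the reference via [oddsRatioWoolf()].  With `adjust_for`, adjusted ORs
#' come from logistic regression on node indicator variables plus the
#' covariates.
#'
#' @param tree a pruned [CartTree-class] with >= 2 terminal nodes.
#' @param data predictor `data.frame` for the subjects to evaluate.
#' @param y case/control indicator aligned with `data`.
#' @param adjust_for optional covariate `data.frame` (numeric columns)
#'   for adjusted node ORs.
#' @return `data.frame` of class `NodeRiskTable`: node id, predicate,
#'   counts, crude OR/CI/p (reference OR fixed at 1), optional adjusted
#'   columns; attribute `n_unroutable` counts excluded subjects.
#' @export
nodeRiskTable <- function(tree, data, y, adjust_for = NULL) {
  y <- as.logical(y)
  leaf <- routeSubjects(tree, data)
  ok <- !is.na(leaf)
  term <- sort(unique(leaf[ok]))
  if (length(term) < 2)
    stop("risk estimation needs at least 2 terminal nodes")
  n_case <- vapply(term, function(id) sum(y[ok] & leaf[ok] == id),
                   numeric(1))
  n_ctrl <- vapply(term, function(id) sum(!y[ok] & leaf[ok] == id),
                   numeric(1))
  out <- nodeRiskFromCounts(n_case, n_ctrl, node_id = term)
  out$predicate <- .nodePredicates(tree)[out$node_id]
  out <- out[, c("node_id", "predicate", "n_control", "n_case",
                 "or", "ci_low", "ci_high", "p", "reference")]
  if (!is.null(adjust_for)) {
    ref <- out$node_id[out$reference]
    nodef <- factor(leaf[ok], levels = c(ref, setdiff(term, ref)))
    ind <- stats::model.matrix(~nodef)[, -1, drop = FALSE]
    colnames(ind) <- paste0("node", setdiff(term, ref))
    covm <- as.matrix(data.frame(lapply(
      as.data.frame(adjust_for)[ok, , drop = FALSE], as.numeric)))
    f <- fitLogistic(y[ok], cbind(ind, covm))
    m <- match(paste0("node", out$node_id), names(f$or))
    out$or_adjusted <- ifelse(is.na(m), 1, f$or[m])
    out$ci_adj_low <- f$ci_low[m]
    out$ci_adj_high <- f$ci_high[m]
    out$p_adjusted <- f$p[m]
  }
  attr(out, "n_unroutable") <- sum(!ok)
  class(out) <- c("NodeRiskTable", "data.frame")
  out
}

#' Terminal-node odds ratios from printed counts
#'
#' The 2x2 arithmetic behind [nodeRiskTable()], applicable directly to a
#' published table of per-node case/control counts: selects the
#' reference node (lowest case fraction; ties -> larger node, then first)
#' and computes each node's crude odds ratio against it.
#'
#' @param n_case,n_control per-node counts.
#' @param node_id node labels (default 1..k).
#' @param reference optional explicit reference node id.
#' @return `data.frame` with per-node OR, Woolf CI and Wald p; the
#'   reference row has OR 1.
#' @export
nodeRiskFromCounts <- function(n_case, n_control, node_id = NULL,
                               reference = NULL) {
  k <- length(n_case)
  stopifnot(length(n_control) == k)
  if (is.null(node_id)) node_id <- seq_len(k)
  frac <- n_case / (n_case + n_control)
  ref_i <- if (is.null(reference)) {
    cand <- which(frac == min(frac))
    cand[order(-(n_case + n_control)[cand], cand)][1]
  } else {
    match(reference, node_id)
  }
  rows <- lapply(seq_len(k), function(i) {
    if (i == ref_i)
      return(data.frame(node_id = node_id[i], n_control = n_control[i],
                        n_case = n_case[i], or = 1, ci_low = NA_real_,
                        ci_high = NA_real_, p = NA_real_, reference = TRUE))
    w <- oddsRatioWoolf(n_case[i], n_control[i],
                        n_case[ref_i], n_control[ref_i])
    data.frame(node_id = node_id[i], n_control = n_control[i],
               n_case = n_case[i], or = w$or, ci_low = w$ci_low,
               ci_high = w$ci_high, p = w$p, reference = FALSE)
  })
  do.call(rbind, rows)
}

#' Assemble the CART predictor table from a cohort
#'
#' Builds the predictor `data.frame` for [growTree()]: genotype columns
#' become 3-level factors (`AA`/`AB`/`BB`), logical covariates stay
#' logical, character covariates become factors and numeric covariates
#' stay numeric.  Subjects with an indeterminate status or a missing
#' value in any used column are dropped (counted in the attribute
#' `n_dropped`).
#'
#' @param cohort a [SnpCohort-class].
#' @param snp_ids genotype predictors.
#' @param env_vars covariate predictors (colData columns).
#' @return List with `data` (predictors), `y` (case indicator),
#'   `subject_id`, and `n_dropped`.
#' @export
cartData <- function(cohort, snp_ids = NULL,
                     env_vars = c("age", "cne", "ppe", "smoking",
                                  "drinking")) {
  if (is.null(snp_ids)) snp_ids <- snpPanel(cohort)$snp_id
  status <- caseStatus(cohort)
  cd <- covariates(cohort)
  df <- data.frame(row.names = colnames(cohort))
  for (s in snp_ids)
    df[[s]] <- factor(genotypes(cohort)[s, ], levels = GENOTYPE_LEVELS)
  for (v in env_vars) {
    x <- cd[[v]]
    if (is.null(x)) stop("unknown covariate: ", v)
    df[[v]] <- if (is.character(x)) factor(x) else x
  }
  keep <- status %in% c("case", "control") & complete.cases(df)
  list(data = df[keep, , drop = FALSE],
       y = status[keep] == "case",
       subject_id = colnames(cohort)[keep],
       n_dropped = sum(!keep))
}
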