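# Pluggable per-person choice-probability models.
#
# A choice model is any object with a `choice_set` (ordered category labels)
# and a predict method returning one probability row per person. The default
# engine is multinomial logistic regression (deterministic, calibrated: the
# average fitted probabilities reproduce the observed class shares); a
# shallow neural network classifier can be dropped in behind the same
# contract.

#' Train a choice-probability model
#'
#' @param data data.frame holding features and the target column.
#' @param features Character vector of feature column names.
#' @param target Name of the categorical target column.
#' @param engine `"multinom"` (default) or `"nnet"` (single-hidden-layer
#'   network with softmax output).
#' @param seed Integer seed (the nnet engine draws random initial weights;
#'   multinom is seeded for reproducibility of its initialization).
#' @param ... Passed to the underlying fitter.
#' @return Object of class `choice_model` with elements `choice_set`,
#'   `features`, and the fitted model.
#' @export
train_choice_model <- function(data, features, target,
                               engine = c("multinom", "nnet"), seed = 1L, ...) {
  engine <- match.arg(engine)
  if (!target %in% names(data)) {
    stopf("target column '%s' not in data", target, class = "actipop_input_error")
  }
  y <- factor(data[[target]])
  if (nlevels(y) < 2L) {
    stopf("target '%s' has a single observed class; cannot train a choice model",
          target, class = "actipop_degenerate_model_error")
  }
  df <- data[, features, drop = FALSE]
  df$.y <- y
  fml <- stats::as.formula(paste(".y ~", paste(features, collapse = " + ")))
  fit <- with_seed(seed, {
    if (engine == "multinom") {
      nnet::multinom(fml, data = df, trace = FALSE, maxit = 200, ...)
    } else {
      nnet::nnet(fml, data = df, size = 5, softmax = FALSE, trace = FALSE,
                 maxit = 300, decay = 1e-3, ...)
    }
  })
  structure(list(engine = engine, fit = fit, features = features,
                 choice_set = levels(y)),
            class = "choice_model")
}

#' A constant choice model (every person gets the same probability row)
#'
#' Mostly useful for degenerate configurations and tests.
#' @param probs Named probability vector (the choice set and its weights).
#' @return A `choice_model`.
#' @export
choice_model_constant <- function(probs) {
  if (abs(sum(probs) - 1) > 1e-9 || any(probs < 0)) {
    stopf("probs must be a probability vector", class = "actipop_input_error")
  }
  structure(list(engine = "constant", probs = probs,
                 choice_set = names(probs)),
            class = "choice_model")
}

#' A functional choice model
#'
#' @param f Function taking a data.frame of persons and returning an
#'   n x K probability matrix (columns in `choice_set` order).
#' @param choice_set Ordered category labels.
#' @return A `choice_model`.
#' @export
choice_model_fun <- function(f, choice_set) {
  structure(list(engine = "fun", f = f, choice_set = choice_set),
            class = "choice_model")
}

#' Predict per-person choice probabilities
#'
#' @param model A `choice_model`.
#' @param newdata data.frame of persons.
#' @return n x K matrix of probabilities, columns named by the choice set;
#'   each row sums to 1.
#' @export
predict_probs <- function(model, newdata) {
  stopifnot(inherits(model, "choice_model"))
  n <- nrow(newdata)
  K <- length(model$choice_set)
  out <- switch(model$engine,
    constant = matrix(rep(model$probs, each = n), n, K,
                      dimnames = list(NULL, model$choice_set)),
    fun = {
      m <- model$f(newdata)
      if (is.null(dim(m))) m <- matrix(m, nrow = n)
      colnames(m) <- model$choice_set
      m
    },
    nnet = {
      pr <- stats::predict(model$fit, newdata = newdata, type = "raw")
      if (ncol(pr) == 1L) pr <- cbind(1 - pr[, 1], pr[, 1])
      colnames(pr) <- model$choice_set
      pr
    },
    multinom = {
      pr <- stats::predict(model$fit, newdata = newdata, type = "probs")
      if (is.null(dim(pr))) {                 # two-class multinom: vector
        if (length(model$choice_set) == 2L) {
          pr <- cbind(1 - pr, pr)
        } else pr <- matrix(pr, nrow = 1)     # single-row prediction
      }
      colnames(pr) <- model$choice_set
      pr
    })
  bad <- abs(rowSums(out) - 1) > 1e-6 | apply(out < -1e-12, 1, any)
  if (any(bad)) {
    stopf("choice model produced invalid probability rows",
          class = "actipop_internal_error")
  }
  pmax(out, 0) / rowSums(pmax(out, 0))
}

#' @export
print.choice_model <- function(x, ...) {
  cat(sprintf("Choice model (%s) over {%s}\n", x$engine,
              paste(x$choice_set, collapse = ", ")))
  invisible(x)
}
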