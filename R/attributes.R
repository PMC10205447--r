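# Stage 1b: advanced attributes via the generative model
# (classifier -> biproportional adjustment -> probabilistic sampling).

#' Biproportionally adjust per-person choice probabilities to category totals
#'
#' IPF on the persons x categories probability matrix with all row targets 1
#' and the given column targets, so each person keeps a proper probability
#' row while the expected category totals match the aggregate controls.
#' Targets are first rescaled proportionally to sum to the number of rows
#' (official counts are integer-rounded and rarely sum exactly). Structural
#' zeros (a person's impossible categories) are preserved.
#'
#' @param probabilities n x K matrix; each row a probability vector.
#' @param targets Numeric vector of K desired category totals (>= 0).
#' @param tol Tolerance on the maximum column-sum residual.
#' @param max_iter Maximum sweeps.
#' @return n x K adjusted matrix (class `adjusted_probs`, attribute
#'   `targets` = the rescaled targets).
#' @export
fit_probabilities <- function(probabilities, targets, tol = 1e-8,
                              max_iter = 2000L) {
  P <- as.matrix(probabilities)
  n <- nrow(P); K <- ncol(P)
  if (length(targets) != K) {
    stopf("need one target per category (%d categories, %d targets)",
          K, length(targets), class = "actipop_input_error")
  }
  if (any(targets < 0) || any(P < 0)) {
    stopf("probabilities and targets must be non-negative",
          class = "actipop_input_error")
  }
  tg <- targets / sum(targets) * n
  mass <- colSums(P)
  dead <- mass == 0 & tg > 0
  if (any(dead)) {
    nm <- colnames(P) %||% as.character(seq_len(K))
    stopf("category '%s' has zero probability mass but a positive target",
          paste(nm[dead], collapse = "', '"), class = "actipop_infeasibility_error")
  }
  it <- 0L
  repeat {
    it <- it + 1L
    cs <- colSums(P)
    fac <- ifelse(cs > 0, tg / cs, 0)
    P <- sweep(P, 2, fac, `*`)
    rs <- rowSums(P)
    P <- P / ifelse(rs > 0, rs, 1)
    r <- max(abs(colSums(P) - tg))
    if (r <= tol * max(1, n / K)) break
    if (it >= max_iter) {
      stopf("probability fitting did not converge in %d iterations (residual %.3g)",
            max_iter, r, class = "actipop_convergence_error")
    }
  }
  structure(P, class = c("adjusted_probs", class(P)), targets = tg)
}

#' Sample one category per person from an adjusted probability matrix
#'
#' @param adjusted n x K matrix of per-person probability rows.
#' @param seed Integer seed.
#' @return Character vector (length n) of sampled category labels.
#' @export
sample_choices <- function(adjusted, seed = NULL) {
  P <- unclass(adjusted)
  with_seed(seed, {
    idx <- sample_rows(P)
    (colnames(P) %||% as.character(seq_len(ncol(P))))[idx]
  })
}

# 2x2 joint employment-by-studenthood targets from two scalar zone controls,
# using the survey's joint structure as the IPF seed.
.joint_emp_stud_targets <- function(n, n_emp, n_stud, survey_joint) {
  n_emp <- min(n_emp, n); n_stud <- min(n_stud, n)
  fit <- ipf_fit(survey_joint + 1e-9,
                 list(c(n - n_emp, n_emp), c(n - n_stud, n_stud)),
                 tol = 1e-9, max_iter = 5000L)
  fit$table
}

# Exponentially tilt car-class shares so the expected number of cars per
# zone matches the observed total. Classes are 0,1,2,3+ cars.
.tilt_car_targets <- function(shares, n, total_cars) {
  k <- 0:3
  mean_target <- total_cars / n
  mean_target <- min(max(mean_target, 1e-6), 3 - 1e-6)
  f <- function(theta) sum(shares * exp(theta * k) * k) /
    sum(shares * exp(theta * k)) - mean_target
  theta <- stats::uniroot(f, c(-50, 50))$root
  w <- shares * exp(theta * k)
  w / sum(w) * n
}

#' Assign advanced attributes to a synthetic population
#'
#' Applies the generative model three times, in sequence, each step
#' conditioning on the previous ones: (1) joint employment-by-studenthood
#' over four combined categories, fitted per zone to the employee and
#' student controls (employment structurally impossible below 17 years);
#' (2) income class over five categories fitted to municipal income counts;
#' (3) personal car count over 0/1/2/3+ fitted per zone so the expected car
#' total matches the zone control. Household car count is aggregated from
#' members (default: maximum, treating the person value as "cars in my
#' household"; `car_aggregate = "sum"` adds them).
#'
#' @param persons Persons with basic attributes and `HId`.
#' @param households Households from [form_households()].
#' @param survey An `actipop_survey` used to train the choice models.
#' @param world The `actipop_world` providing zone/municipal controls.
#' @param seed Integer seed.
#' @param car_aggregate `"max"` or `"sum"`.
#' @return list with completed `persons` (employment, studenthood,
#'   income_class, n_cars) and `households` (n_cars filled).
#' @export
assign_advanced_attributes <- function(persons, households, survey, world,
                                       seed = 1L, car_aggregate = c("max", "sum")) {
  car_aggregate <- match.arg(car_aggregate)
  sp <- survey$persons
  hh_size <- households$size[match(persons$HId, households$HId)]
  hh_size[is.na(hh_size)] <- 1L
  feats <- data.frame(age = persons$age,
                      gender = factor(persons$gender, c("Male", "Female")),
                      marital = factor(persons$marital_status, CIVIL_LEVELS),
                      hh_size = hh_size)
  sp_train <- data.frame(age = sp$age,
                         gender = factor(sp$gender, c("Male", "Female")),
                         marital = factor(sp$civil_status, CIVIL_LEVELS),
                         hh_size = 1L)  # survey household size not modelled

  # ---- (1) joint employment x studenthood ----------------------------------
  es_labels <- c("none", "emp", "stud", "both")
  sp_train$empstud <- es_labels[1L + sp$employment + 2L * sp$studenthood]
  m1 <- train_choice_model(sp_train, c("age", "gender", "marital"),
                           "empstud", seed = derive_seed(seed, 101))
  P1 <- matrix(0, nrow(persons), 4, dimnames = list(NULL, es_labels))
  P1[, m1$choice_set] <- predict_probs(m1, feats)
  # structural zero: no employment at 16 or below
  young <- persons$age <= 16
  P1[young, c("emp", "both")] <- 0
  P1 <- P1 / rowSums(P1)
  survey_joint <- table(factor(sp$employment, 0:1), factor(sp$studenthood, 0:1))
  choice1 <- rep(NA_character_, nrow(persons))
  for (zid in unique(persons$zone)) {
    zi <- which(persons$zone == zid)
    zrow <- world$zones[world$zones$zone_id == zid, ]
    tg4 <- .joint_emp_stud_targets(length(zi), zrow$n_employees,
                                   zrow$n_students, survey_joint)
    targets <- c(none = tg4[1, 1], emp = tg4[2, 1],
                 stud = tg4[1, 2], both = tg4[2, 2])
    adj <- fit_probabilities(P1[zi, , drop = FALSE], targets)
    choice1[zi] <- sample_choices(adj, seed = derive_seed(seed, 200 + match(zid, world$zones$zone_id)))
  }
  persons$employment <- as.integer(choice1 %in% c("emp", "both"))
  persons$studenthood <- as.integer(choice1 %in% c("stud", "both"))

  # ---- (2) income class, fitted at the municipal level ---------------------
  feats$employment <- persons$employment
  feats$studenthood <- persons$studenthood
  sp_train$employment <- sp$employment
  sp_train$studenthood <- sp$studenthood
  sp_train$income <- factor(sp$income_class, INCOME_CLASSES)
  m2 <- train_choice_model(sp_train,
                           c("age", "gender", "marital", "employment", "studenthood"),
                           "income", seed = derive_seed(seed, 102))
  P2 <- matrix(0, nrow(persons), 5, dimnames = list(NULL, INCOME_CLASSES))
  P2[, m2$choice_set] <- predict_probs(m2, feats)
  persons$income_class <- NA_character_
  for (mid in unique(persons$municipality)) {
    mi <- which(persons$municipality == mid)
    ic <- world$income_counts[world$income_counts$municipality_id == mid, ]
    targets <- ic$count[match(INCOME_CLASSES, ic$income_class)]
    adj <- fit_probabilities(P2[mi, , drop = FALSE], targets)
    persons$income_class[mi] <-
      sample_choices(adj, seed = derive_seed(seed, 300 + match(mid, unique(persons$municipality))))
  }

  # ---- (3) cars: 0/1/2/3+ per household, tilted to the zone car total ------
  # Cars are a household good (the person value reports the cars of one's
  # household), so the choice model is applied to one reference row per
  # household -- its oldest member plus the household size -- and the
  # adjusted matrix is fitted so the expected zone car total matches the
  # control; members then inherit the household value.
  feats$income_rank <- match(persons$income_class, INCOME_CLASSES)
  sp_train$income_rank <- match(sp$income_class, INCOME_CLASSES)
  sp_train$carclass <- factor(pmin(sp$n_cars, 3L), 0:3)
  m3 <- train_choice_model(sp_train,
                           c("age", "gender", "marital", "employment", "income_rank"),
                           "carclass", seed = derive_seed(seed, 103))
  # reference person: oldest member of each household
  ref <- tapply(seq_len(nrow(persons)),
                factor(persons$HId, levels = households$HId),
                function(ii) ii[which.max(persons$age[ii])])
  ref <- as.integer(ref)
  P3h <- matrix(0, nrow(households), 4, dimnames = list(NULL, as.character(0:3)))
  P3h[, m3$choice_set] <- predict_probs(m3, feats[ref, , drop = FALSE])
  hh_zone <- persons$zone[ref]
  survey_car_shares <- as.numeric(table(factor(pmin(sp$n_cars, 3L), 0:3)))
  survey_car_shares <- survey_car_shares / sum(survey_car_shares)
  hh_cars <- rep(NA_integer_, nrow(households))
  for (zid in unique(hh_zone)) {
    hi <- which(hh_zone == zid)
    zrow <- world$zones[world$zones$zone_id == zid, ]
    targets <- .tilt_car_targets(survey_car_shares, length(hi), zrow$n_cars)
    adj <- fit_probabilities(P3h[hi, , drop = FALSE], targets)
    hh_cars[hi] <- as.integer(
      sample_choices(adj, seed = derive_seed(seed, 400 + match(zid, world$zones$zone_id))))
  }
  persons$n_cars <- hh_cars[match(persons$HId, households$HId)]

  agg <- if (car_aggregate == "max") max else sum
  hc <- tapply(persons$n_cars, factor(persons$HId, levels = households$HId), agg)
  hc[is.na(hc)] <- 0
  households$n_cars <- as.integer(hc)
  list(persons = persons, households = households)
}
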