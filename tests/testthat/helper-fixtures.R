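# Shared fixtures and independent oracles.

subtypes <- c("neglect", "physical", "emotional", "sexual")

# A minimal hand-built cohort row; override any field.
blank_record <- function(id = 1L, gender = "woman", age = 40L,
                         income = 2500, ...) {
  rec <- tibble::tibble(id = id, gender = gender, age = age, income = income)
  for (s in subtypes) for (k in 1:5)
    rec[[paste0("act_", s, "_", k)]] <- 0L
  for (s in subtypes) rec[[paste0("ages_", s)]] <- ""
  rec$frequency_answer <- NA_character_
  rec$severity_answer <- NA_character_
  for (d in c("overweight", "diabetes", "cancer", "hypertension", "mi",
              "copd", "stroke"))
    rec[[paste0("dis_", d)]] <- 0L
  over <- list(...)
  for (nm in names(over)) rec[[nm]] <- over[[nm]]
  rec
}

# All permutations of 1..n (n <= 8), one per row.
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 1
  for (i in seq_len(nrow(sub))) for (pos in seq_len(n)) {
    out[r, ] <- append(sub[i, ], n, after = pos - 1)
    r <- r + 1
  }
  out
}

# Exact permutation p-value of the standardized linear-statistic test,
# by full enumeration.  Independent of the C++ path: statistics are
# computed from the direct formulas.
exact_assoc_p <- function(x, y) {
  n <- length(y)
  stat <- function(yp) {
    if (is.factor(x)) {
      k <- nlevels(x)
      cnt <- tabulate(as.integer(x), k)
      mu <- mean(yp)
      vh <- mean((yp - mu)^2)
      T <- tapply(yp, x, sum)
      T[is.na(T)] <- 0
      d <- as.numeric(T - cnt * mu)
      V <- (vh / (n - 1)) * (n * diag(cnt) - outer(cnt, cnt))
      ei <- eigen(V, symmetric = TRUE)
      keep <- ei$values > max(ei$values) * 1e-10
      sum((t(ei$vectors[, keep, drop = FALSE]) %*% d)^2 /
            ei$values[keep])
    } else {
      (n - 1) * suppressWarnings(cor(x, yp))^2
    }
  }
  obs <- stat(y)
  perms <- all_perms(n)
  ps <- apply(perms, 1, function(idx) stat(y[idx]))
  mean(ps >= obs - 1e-12)
}

# Walk a single tree in R and return the leaf mean for one row (structural
# oracle for prediction).
r_tree_predict <- function(tree, xrow) {
  node <- 1
  repeat {
    v <- tree$var[node]
    if (v < 0) return(tree$value[node])
    x <- xrow[[v + 1]]
    node <- if (tree$mask[node] < 0) {
      if (x <= tree$cut[node]) tree$left[node] + 1 else tree$right[node] + 1
    } else {
      if (bitwAnd(bitwShiftR(tree$mask[node], as.integer(x)), 1L) == 1L)
        tree$left[node] + 1
      else tree$right[node] + 1
    }
  }
}

# Feature tibble built directly (bypassing the generator) with the standard
# column names, for pipeline-level unit tests.
synthetic_features <- function(n = 200, seed = 1) {
  withr::with_seed(seed, {
    f <- tibble::tibble(
      id = seq_len(n),
      gender = sample(c("woman", "man"), n, replace = TRUE),
      age = round(runif(n, 18, 90)),
      income = runif(n, 500, 6000)
    )
    for (s in subtypes) f[[paste0("s_", s)]] <- rbinom(n, 1, 0.2)
    f$multiplicity <- as.integer(f$s_neglect + f$s_physical +
                                   f$s_emotional + f$s_sexual)
    tm <- matrix(0L, n, 18)
    for (i in seq_len(n)) if (f$multiplicity[i] > 0) {
      o <- sample(1:14, 1)
      tm[i, o:min(o + sample(0:5, 1), 18)] <- 1L
    }
    colnames(tm) <- paste0("t_", 1:18)
    f <- dplyr::bind_cols(f, tibble::as_tibble(tm))
    f$duration <- as.integer(rowSums(tm))
    f$frequency <- ifelse(f$multiplicity > 0, sample(1:3, n, TRUE), 0L)
    f$severity <- ifelse(f$multiplicity > 0, sample(0:3, n, TRUE), 0L)
    f$multimorbidity <- pmin(7L, rbinom(n, 7, plogis(-2 + 0.1 * f$duration)))
    structure(f, roles = cmforest:::default_roles(),
              class = c("cm_features", class(f)))
  })
}
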