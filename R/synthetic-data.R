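#' @title Synthetic Pima-like clinical data
#'
#' @description
#' `sim_pima()` draws a seeded synthetic diabetes-style tabular dataset with
#' the classic nine-column Pima schema: eight integer clinical predictors
#' (number of pregnancies, plasma glucose, blood pressure, skin-fold
#' thickness, serum insulin, body-mass index, diabetes pedigree function,
#' age) and a binary `Outcome`.  Features are correlated through a single
#' latent "metabolic severity" factor and truncated/rounded to plausible
#' integer ranges; the label is Bernoulli with a logistic model on the
#' standardized features under a fixed, documented ground-truth coefficient
#' vector, with the intercept calibrated by bisection so the marginal
#' positive rate matches `positive_rate`.
#'
#' The column means, spreads, ranges, factor loadings and ground-truth
#' coefficients are fixture constants chosen to give a learnable task with
#' plausible magnitudes; they are not estimates of the real Pima cohort
#' (in particular the pedigree function is represented on a x100 integer
#' scale so that all eight predictors are integers).
#'
#' @param n number of samples (>= 1).
#' @param seed integer seed; generation is bit-reproducible given
#'   `(n, seed, positive_rate, noise_scale)`.
#' @param positive_rate target marginal frequency of `Outcome == 1`,
#'   strictly between 0 and 1.
#' @param noise_scale multiplier on the idiosyncratic (non-shared) feature
#'   noise; 1 reproduces the nominal column spreads.
#' @return an object of class `clinical_dataset`: a list with `features`
#'   (integer matrix, n x 8, named columns), `labels` (integer 0/1 vector)
#'   and `provenance` (generator parameters, seed, ground-truth
#'   coefficients, calibrated intercept, and the nominal centers/scales
#'   used for standardization).
#' @examples
#' ds <- sim_pima(200, seed = 1)
#' table(ds$labels)
#' @export
sim_pima <- function(n, seed, positive_rate = 0.35, noise_scale = 1) {
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != floor(n))
    stop_param("'n' must be a positive integer")
  if (!is.numeric(positive_rate) || positive_rate <= 0 || positive_rate >= 1)
    stop_param("'positive_rate' must be in (0, 1)")
  if (!is.numeric(noise_scale) || noise_scale < 0)
    stop_param("'noise_scale' must be non-negative")
  spec <- pima_schema()
  p <- nrow(spec)
  x <- with_seed(derive_seed(seed, "sim_pima", n, positive_rate, noise_scale), {
    z <- rnorm(n)                       # shared latent severity factor
    e <- matrix(rnorm(n * p), n, p)
    raw <- matrix(0, n, p, dimnames = list(NULL, spec$name))
    for (j in seq_len(p)) {
      lam <- spec$loading[j]
      u <- lam * z + sqrt(1 - lam^2) * noise_scale * e[, j]
      v <- spec$mean[j] + spec$sd[j] * u
      raw[, j] <- round(pmin(pmax(v, spec$lower[j]), spec$upper[j]))
    }
    raw
  })
  xs <- scale(x, center = spec$mean, scale = spec$sd)
  beta <- pima_truth_beta()
  eta0 <- drop(xs %*% beta)
  bias <- calibrate_bias(eta0, positive_rate)
  labels <- with_seed(derive_seed(seed, "sim_pima_labels", n), {
    as.integer(runif(n) < plogis(eta0 + bias))
  })
  new_clinical_dataset(
    features = x, labels = labels,
    provenance = list(generator = "sim_pima", n = n, seed = seed,
                      positive_rate = positive_rate,
                      noise_scale = noise_scale,
                      beta = beta, bias = bias,
                      centers = spec$mean, scales = spec$sd)
  )
}

# Fixture constants for the eight predictors: nominal center/spread,
# truncation range, and loading on the shared latent factor.
pima_schema <- function() {
  data.frame(
    name = c("Pregnanci", "Glucose", "BloodPressure", "SkinThickness",
             "Insulin", "BMI", "DiabetesPedigreeFunction", "Age"),
    mean = c(3.8, 121, 69, 21, 80, 32, 47, 33),
    sd   = c(3.2, 31, 18, 15, 105, 7, 33, 11),
    lower = c(0, 44, 24, 0, 0, 18, 8, 21),
    upper = c(17, 199, 122, 99, 846, 67, 250, 81),
    loading = c(0.25, 0.55, 0.35, 0.45, 0.50, 0.50, 0.20, 0.40),
    stringsAsFactors = FALSE
  )
}

# Ground-truth coefficients on the standardized feature scale.  Glucose and
# BMI dominate; every sign is positive so sign-recovery checks are sharp.
pima_truth_beta <- function() {
  c(Pregnanci = 0.30, Glucose = 1.60, BloodPressure = 0.20,
    SkinThickness = 0.10, Insulin = 0.30, BMI = 0.90,
    DiabetesPedigreeFunction = 0.50, Age = 0.60)
}

# Bisection on the intercept so that mean(plogis(eta0 + b)) = target.
calibrate_bias <- function(eta0, target, tol = 1e-10) {
  f <- function(b) mean(plogis(eta0 + b)) - target
  lo <- -30; hi <- 30
  for (i in 1:100) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

new_clinical_dataset <- function(features, labels, provenance = list()) {
  features <- as.matrix(features)
  if (ncol(features) != 8)
    stop_param("'features' must have exactly 8 columns")
  labels <- as.integer(labels)
  if (length(labels) != nrow(features))
    stop_param("'labels' length must match rows of 'features'")
  if (length(labels) && !all(labels %in% c(0L, 1L)))
    stop_param("'labels' must be binary 0/1")
  structure(list(features = features, labels = labels,
                 provenance = provenance),
            class = "clinical_dataset")
}

#' @export
print.clinical_dataset <- function(x, ...) {
  cat(sprintf("<clinical_dataset> %d samples x %d features, %.1f%% positive\n",
              nrow(x$features), ncol(x$features),
              100 * mean(x$labels)))
  invisible(x)
}

# Row subset preserving provenance.
ds_subset <- function(ds, idx) {
  new_clinical_dataset(ds$features[idx, , drop = FALSE], ds$labels[idx],
                       ds$provenance)
}

#' Split a clinical dataset into train and test sets
#'
#' Draws `round(n * test_fraction)` rows (without replacement, under a
#' named seed substream) as the test set; the remainder is the training
#' set.  The two parts are disjoint and exhaustive.
#'
#' @param ds a `clinical_dataset`.
#' @param test_fraction fraction of rows held out, in (0, 1).
#' @param seed integer seed.
#' @return list with elements `train` and `test`, both `clinical_dataset`.
#' @examples
#' sp <- train_test_split(sim_pima(768, 1), 0.3, seed = 2)
#' nrow(sp$train$features)  # 538
#' @export
train_test_split <- function(ds, test_fraction, seed) {
  stopifnot(inherits(ds, "clinical_dataset"))
  if (!is.numeric(test_fraction) || test_fraction <= 0 || test_fraction >= 1)
    stop_param("'test_fraction' must be in (0, 1)")
  n <- nrow(ds$features)
  n_test <- round(n * test_fraction)
  idx <- with_seed(derive_seed(seed, "train_test_split", n, test_fraction),
                   sample.int(n, n_test))
  list(train = ds_subset(ds, setdiff(seq_len(n), idx)),
       test = ds_subset(ds, sort(idx)))
}

#' Partition a dataset evenly across simulated devices
#'
#' Randomly shuffles the rows and cuts them into `K` contiguous chunks
#' whose sizes differ by at most one (the first `n %% K` shards get the
#' extra row), emulating an even split of a training set across devices.
#'
#' @param ds a `clinical_dataset` (the training set).
#' @param K number of devices; must satisfy `1 <= K <= n`.
#' @param seed integer seed for the shuffle (a named substream,
#'   independent of training/noise streams).
#' @return an object of class `device_partition`: list with `shards`
#'   (list of K `clinical_dataset`s) and `K`.
#' @export
partition_devices <- function(ds, K, seed) {
  stopifnot(inherits(ds, "clinical_dataset"))
  n <- nrow(ds$features)
  if (!is.numeric(K) || length(K) != 1 || K < 1 || K != floor(K))
    stop_param("'K' must be a positive integer")
  if (K > n)
    stop_param("'K' (", K, ") exceeds the number of samples (", n, ")")
  perm <- with_seed(derive_seed(seed, "partition_devices", n, K),
                    sample.int(n))
  base <- n %/% K
  extra <- n %% K
  sizes <- rep(base, K) + c(rep(1L, extra), rep(0L, K - extra))
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  shards <- lapply(seq_len(K), function(k)
    ds_subset(ds, perm[starts[k]:ends[k]]))
  structure(list(shards = shards, K = K), class = "device_partition")
}

#' @export
print.device_partition <- function(x, ...) {
  sizes <- vapply(x$shards, function(s) nrow(s$features), 0L)
  cat(sprintf("<device_partition> K=%d shards, sizes %d..%d\n",
              x$K, min(sizes), max(sizes)))
  invisible(x)
}

#' Read or write a Pima-format CSV
#'
#' The nine-column comma-separated format with header
#' `Pregnanci,Glucose,BloodPressure,SkinThickness,Insulin,BMI,DiabetesPedigreeFunction,Age,Outcome`.
#' `read_pima_csv()` accepts any file with that schema (for example the
#' public Pima diabetes CSV after renaming its header); nothing else in
#' the package depends on external data.
#'
#' @param path file path.
#' @return `read_pima_csv()` returns a `clinical_dataset`.
#' @export
read_pima_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  want <- c(pima_schema()$name, "Outcome")
  if (!identical(names(df), want))
    stop_param("CSV header must be exactly: ", paste(want, collapse = ","))
  new_clinical_dataset(as.matrix(df[, 1:8]), df$Outcome,
                       provenance = list(generator = "csv", path = path))
}

#' @param ds a `clinical_dataset` to write.
#' @rdname read_pima_csv
#' @export
write_pima_csv <- function(ds, path) {
  stopifnot(inherits(ds, "clinical_dataset"))
  df <- as.data.frame(ds$features)
  df$Outcome <- ds$labels
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
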