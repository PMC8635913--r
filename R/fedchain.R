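#' Experiment configuration
#'
#' Bundles and validates every knob of the simulator.  The defaults
#' reproduce the reference experimental conditions: 20 devices over a
#' 70:30 split of 768 synthetic samples, batch size 64 (silently reduced
#' to the shard size), 20 local iterations, adaptive-DP hyperparameters
#' `G = 1e-6`, `beta = 1.2`, `sigma = 4`, `gamma = 0.1`, `C = 3`, budget
#' `epsilon = 3` at `delta = 1e-4`, committee of `M = 5` verifiers drawn
#' from 10 miners, and multi-KRUM verification with `f = ceil(0.3 R)`.
#'
#' @param n,positive_rate,noise_scale synthetic-data settings (ignored
#'   when data is supplied to [fedchain()] directly).
#' @param test_fraction held-out fraction.
#' @param K number of devices.
#' @param T_max maximum training rounds.
#' @param n_miners miner (edge-node) count.
#' @param M verification-committee size.
#' @param arch_id model backend (`"logistic"` or `"tabular_mlp"`).
#' @param batch_size,local_iterations,lr local SGD settings.
#' @param G,beta,sigma,gamma,C adaptive-DP hyperparameters (see
#'   [clipper_state()]).
#' @param epsilon,delta privacy budget; `check_budget = FALSE` runs a
#'   fixed horizon regardless of spend.
#' @param composition_mode,mechanism_mode,lambdas,per_iteration_accounting
#'   accountant settings (see [moment_ledger()], [mechanism_spec()]).
#' @param verification enable multi-KRUM screening; with `FALSE` every
#'   submitted update is accepted (the undefended pipeline).
#' @param krum_f assumed Byzantine count; `NULL` = `ceil(0.3 R)` per
#'   round.
#' @param krum_squared use squared distances in [krum_scores()].
#' @param poisoned_fraction fraction of label-flipped devices.
#' @param n_malicious_verifiers miners behaving maliciously (capped below
#'   `n_miners / 3`).
#' @param initial_reputation genesis reputation of every party.
#' @param conv_tol,conv_patience convergence rule: stop after
#'   `conv_patience` consecutive rounds with relative training-loss
#'   change below `conv_tol`.
#' @param seed master seed; all substreams (data, init, batching, noise,
#'   attack, keys) are derived from it by name.
#' @return object of class `fedchain_config`.
#' @export
fedchain_config <- function(n = 768, positive_rate = 0.35, noise_scale = 1,
                            test_fraction = 0.3, K = 20, T_max = 50,
                            n_miners = 10, M = 5, arch_id = "logistic",
                            batch_size = 64, local_iterations = 20,
                            lr = 0.5, G = 1e-6, beta = 1.2, sigma = 4,
                            gamma = 0.1, C = 3, epsilon = 3, delta = 1e-4,
                            check_budget = TRUE,
                            composition_mode = "sum_over_devices_and_rounds",
                            mechanism_mode = "paper_printed",
                            lambdas = 1:100,
                            per_iteration_accounting = FALSE,
                            verification = TRUE, krum_f = NULL,
                            krum_squared = FALSE, poisoned_fraction = 0,
                            n_malicious_verifiers = 0,
                            initial_reputation = 10,
                            conv_tol = 1e-4, conv_patience = 5, seed = 1) {
  stopifnot(K >= 1, T_max >= 1, M >= 1, n_miners >= M,
            batch_size >= 1, local_iterations >= 1, lr >= 0)
  if (n_malicious_verifiers >= n_miners / 3)
    stop_param("malicious verifiers must stay below 1/3 of the miners")
  if (!arch_id %in% c("logistic", "tabular_mlp"))
    stop_param("training backend must be 'logistic' or 'tabular_mlp'")
  cfg <- as.list(environment())
  structure(cfg, class = "fedchain_config")
}

#' @export
print.fedchain_config <- function(x, ...) {
  cat(sprintf(paste0("<fedchain_config> K=%d T=%d M=%d arch=%s sigma=%g ",
                     "C=%g eps=%g verification=%s poisoned=%.0f%%\n"),
              x$K, x$T_max, x$M, x$arch_id, x$sigma, x$C, x$epsilon,
              x$verification, 100 * x$poisoned_fraction))
  invisible(x)
}

#' Run a blockchain-coordinated federated learning experiment
#'
#' The end-to-end driver.  Each round: every non-blacklisted device
#' trains locally and uploads a clipped, noised, signed update; a
#' reputation-weighted committee selected by consistent hashing screens
#' the pool with multi-KRUM and endorses the qualified updates by
#' majority signature; a hash-derived leader assembles the block, the
#' committee approves it (> 2/3), and every device applies the mean of
#' the block's qualified updates to its model; finally the clipping prior,
#' the moments accountant, and the reputation table are updated.  The run
#' stops at the round limit, on privacy-budget exhaustion, or on
#' convergence of the training loss.
#'
#' @param config a [fedchain_config()].
#' @param data optional `clinical_dataset` to use instead of the
#'   synthetic generator (split and partitioned according to `config`).
#' @param chain_dir optional directory; when given, the block chain is
#'   persisted there with [write_chain()].
#' @return an object of class `fedchain`: the fitted global model plus
#'   the full round history.  Components include `records` (one row per
#'   round: clipping threshold, qualified count, committee, leader, spent
#'   epsilon, accuracy, attack success rate, detection precision/recall,
#'   blacklist size), `params`, `chain`, `reputation`, `moments`, and
#'   `stop_reason`.  Methods: `print`, `summary`, `coef`, `predict`,
#'   `plot`, `residuals`.
#' @examples
#' \donttest{
#' fit <- fedchain(fedchain_config(n = 300, T_max = 3, sigma = 0,
#'                                 check_budget = FALSE, seed = 7))
#' fit
#' }
#' @export
fedchain <- function(config = fedchain_config(), data = NULL,
                     chain_dir = NULL) {
  stopifnot(inherits(config, "fedchain_config"))
  seed <- config$seed

  ## data
  ds <- data %||% sim_pima(config$n, seed,
                           positive_rate = config$positive_rate,
                           noise_scale = config$noise_scale)
  sp <- train_test_split(ds, config$test_fraction, seed)
  prep <- feature_prep(sp$train)
  part <- partition_devices(sp$train, config$K, seed)
  device_ids <- paste0("d", seq_len(config$K))
  miner_ids <- paste0("m", seq_len(config$n_miners))

  ## adversary
  mal_verifiers <- if (config$n_malicious_verifiers > 0)
    miner_ids[seq_len(config$n_malicious_verifiers)] else character()
  atk <- attack_config(config$K, config$poisoned_fraction, seed,
                       device_ids = device_ids,
                       malicious_verifier_ids = mal_verifiers)
  part <- apply_attack(part, atk)

  ## genesis
  all_ids <- c(device_ids, miner_ids)
  keys <- party_keys(all_ids, derive_seed(seed, "keys"))
  table <- reputation_table(all_ids,
                            c(rep("device", config$K),
                              rep("miner", config$n_miners)),
                            initial = config$initial_reputation)
  w <- init_params(config$arch_id, seed)
  genesis <- build_genesis(w, config$T_max, keys, table)
  chain <- list(genesis)

  clipper <- clipper_state(gamma = config$gamma, beta = config$beta,
                           fixed_C = config$C,
                           prior_threshold = config$G, sigma = config$sigma)
  moments <- moment_ledger(config$lambdas, config$composition_mode)
  budget <- privacy_budget(config$epsilon, config$delta)

  records <- list()
  stop_reason <- "max_rounds"
  flat_streak <- 0L
  prev_loss <- NA_real_

  for (t in seq_len(config$T_max)) {
    last_hash <- chain[[length(chain)]]$hash
    C_t <- clipping_threshold(clipper)
    active <- intersect(device_ids, active_devices(table))
    active_idx <- match(active, device_ids)

    ## local training + DP release + signed transactions
    pool <- NULL
    txs <- list()
    qv <- numeric(0)
    for (k in active_idx) {
      shard <- part$shards[[k]]
      u <- local_train(w, shard, config$batch_size,
                       config$local_iterations, config$lr,
                       seed = derive_seed(seed, "batch", t, k),
                       prep = prep, device_id = device_ids[k], round = t)
      noised <- add_noise(clip_gradient(u$gradient, C_t), C_t,
                          config$sigma, seed, device_id = k, round = t)
      pool <- rbind(pool, noised)
      qv <- c(qv, min(1, config$batch_size / nrow(shard$features)))
      txs[[device_ids[k]]] <- list(
        device_id = device_ids[k], gradient = noised,
        device_sig = sign_bytes(keys, device_ids[k],
                                tx_message(t, device_ids[k], noised)))
    }
    rownames(pool) <- active
    R <- length(active)

    ## committee
    committee <- tryCatch(select_committee(last_hash, table, config$M),
                          error = function(e) e)
    if (inherits(committee, "error")) {
      stop_reason <- paste("consensus_error:", conditionMessage(committee))
      break
    }
    leader <- select_leader(committee, last_hash)

    ## verification
    f_nominal <- config$krum_f %||% ceiling(0.3 * R)
    f_eff <- max(0L, min(f_nominal, R - 3L))
    if (config$verification && R >= 3) {
      ver <- endorse_and_accept(pool, f_eff, committee, keys,
                                malicious_verifiers = mal_verifiers,
                                squared = config$krum_squared)
      accepted <- ver$accepted
      votes <- ver$votes
      endorsements <- ver$endorsements
    } else {
      accepted <- active
      votes <- stats::setNames(rep(list(active), length(committee)),
                               committee)
      msgs <- lapply(active, function(d)
        ser_doubles(pool[match(d, active), ]))
      endorsements <- stats::setNames(lapply(seq_along(active), function(i)
        lapply(committee, function(v)
          list(verifier = v, sig = sign_bytes(keys, v, msgs[[i]])))),
        active)
    }
    rejected <- setdiff(active, accepted)

    ## block assembly and approval
    accepted_txs <- lapply(accepted, function(d) {
      tx <- txs[[d]]
      tx$endorsements <- endorsements[[d]]
      tx
    })
    candidate <- build_block(t, last_hash, accepted_txs, committee,
                             leader, keys)
    res <- approve_block(candidate, committee, keys,
                         malicious_verifiers = mal_verifiers)
    block <- res$block
    chain[[length(chain) + 1L]] <- block

    ## global update
    n_qual <- length(block$transactions)
    if (n_qual > 0) {
      gbar <- Reduce(`+`, lapply(block$transactions, `[[`, "gradient")) /
        n_qual
      w$values <- w$values - gbar
      clipper <- update_prior(clipper, gbar)
    }

    ## accountant: one noised release per submitting device
    rounds_mult <- if (config$per_iteration_accounting)
      config$local_iterations else 1
    s_eff <- if (config$mechanism_mode == "paper_printed")
      C_t * config$sigma else config$sigma
    if (config$sigma > 0 && R > 0) {
      for (qu in unique(qv)) {
        spec <- mechanism_spec(qu, s_eff, mode = config$mechanism_mode)
        moments <- accumulate_moments(moments, spec,
                                      devices = sum(qv == qu),
                                      rounds = rounds_mult)
      }
    }
    spent <- epsilon_for_delta(moments, config$delta)

    ## reputation: a verifier is "correct" when its endorsed set matches
    ## the majority-endorsed set (the verification verdict, independent of
    ## whether the candidate block survived approval)
    verifier_ok <- vapply(committee, function(v)
      setequal(votes[[v]], accepted), TRUE)
    table <- update_reputation(table, list(
      plus = c(intersect(accepted, block_accepted_ids(block)),
               committee[verifier_ok]),
      minus = c(rejected, committee[!verifier_ok])))

    ## metrics
    ev <- evaluate_model(w, sp$test, prep)
    train_loss <- dataset_loss(w, sp$train, prep)
    pois <- atk$poisoned_device_ids
    detected <- union(intersect(rejected, pois),
                      intersect(pois, table$blacklist))
    recall <- if (length(pois)) length(detected) / length(pois) else NA_real_
    precision <- if (length(rejected))
      length(intersect(rejected, pois)) / length(rejected) else NA_real_

    records[[t]] <- data.frame(
      round = t, C_t = C_t, n_active = R, n_qualified = n_qual,
      rejected = paste(rejected, collapse = ";"),
      committee = paste(committee, collapse = ";"), leader = leader,
      block_valid = res$valid, spent_epsilon = spent,
      train_loss = train_loss, accuracy = ev$accuracy,
      attack_success_rate = ev$attack_success_rate,
      detection_precision = precision, detection_recall = recall,
      blacklist_size = length(table$blacklist),
      stringsAsFactors = FALSE)

    ## stopping rules
    if (config$check_budget && is_exhausted(budget, moments)) {
      stop_reason <- "budget_exhausted"
      break
    }
    if (is.finite(train_loss) && is.finite(prev_loss)) {
      rel <- abs(train_loss - prev_loss) / max(abs(prev_loss), 1e-12)
      flat_streak <- if (rel < config$conv_tol) flat_streak + 1L else 0L
      if (flat_streak >= config$conv_patience) {
        stop_reason <- "converged"
        break
      }
    }
    prev_loss <- train_loss
  }

  records <- do.call(rbind, records)
  if (!is.null(chain_dir)) write_chain(chain, chain_dir)
  structure(list(config = config, records = records, params = w,
                 prep = prep, chain = chain, keys = keys,
                 reputation = table, clipper = clipper, moments = moments,
                 attack = atk, stop_reason = stop_reason,
                 data = list(train = sp$train, test = sp$test,
                             partition = part)),
            class = "fedchain")
}

block_accepted_ids <- function(block) {
  vapply(block$transactions, `[[`, "", "device_id")
}

#' @export
print.fedchain <- function(x, ...) {
  r <- x$records
  last <- r[nrow(r), ]
  cat("Blockchain-coordinated federated learning run\n")
  cat(sprintf("  rounds: %d (%s)   devices: %d   backend: %s\n",
              nrow(r), x$stop_reason, x$config$K, x$config$arch_id))
  cat(sprintf("  final accuracy: %.3f   attack success rate: %.3f\n",
              last$accuracy, last$attack_success_rate))
  cat(sprintf("  spent epsilon: %.3f (delta = %g)   blacklist: %d\n",
              last$spent_epsilon, x$config$delta, last$blacklist_size))
  invisible(x)
}

#' @export
summary.fedchain <- function(object, last = 10, ...) {
  r <- object$records
  tail_r <- r[r$round > max(0, max(r$round) - last), ]
  out <- list(
    config = object$config, rounds = nrow(r),
    stop_reason = object$stop_reason,
    final_accuracy = r$accuracy[nrow(r)],
    tail_accuracy = mean(tail_r$accuracy),
    tail_asr = mean(tail_r$attack_success_rate),
    spent_epsilon = r$spent_epsilon[nrow(r)],
    mean_qualified = mean(r$n_qualified),
    detection_precision = mean(r$detection_precision, na.rm = TRUE),
    detection_recall = mean(r$detection_recall, na.rm = TRUE),
    blacklist = object$reputation$blacklist)
  class(out) <- "summary.fedchain"
  out
}

#' @export
print.summary.fedchain <- function(x, ...) {
  print(x$config)
  cat(sprintf("rounds run: %d (%s)\n", x$rounds, x$stop_reason))
  cat(sprintf("final / last-10 accuracy: %.3f / %.3f\n",
              x$final_accuracy, x$tail_accuracy))
  cat(sprintf("last-10 attack success rate: %.3f\n", x$tail_asr))
  cat(sprintf("spent epsilon: %.3f   mean qualified/round: %.1f\n",
              x$spent_epsilon, x$mean_qualified))
  if (!is.nan(x$detection_recall))
    cat(sprintf("poison detection precision/recall: %.2f / %.2f\n",
                x$detection_precision, x$detection_recall))
  if (length(x$blacklist))
    cat("blacklisted:", paste(x$blacklist, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.fedchain <- function(object, ...) {
  v <- object$params$values
  if (object$params$arch_id == "logistic")
    names(v) <- c(pima_schema()$name, "(bias)")
  v
}

#' @export
predict.fedchain <- function(object, newdata = NULL,
                             type = c("class", "prob"), ...) {
  type <- match.arg(type)
  feats <- if (is.null(newdata)) object$data$test$features
  else if (inherits(newdata, "clinical_dataset")) newdata$features
  else as.matrix(newdata)
  p <- predict_prob(object$params, feats, object$prep)
  if (type == "prob") p else as.integer(p > 0.5)
}

#' @export
residuals.fedchain <- function(object, ...) {
  test <- object$data$test
  test$labels - predict_prob(object$params, test$features, object$prep)
}

#' @export
plot.fedchain <- function(x, ...) {
  r <- x$records
  op <- par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  plot(r$round, r$accuracy, type = "l", ylim = c(0, 1),
       xlab = "round", ylab = "fraction", main = "model quality")
  lines(r$round, r$attack_success_rate, lty = 2)
  legend("topleft", c("accuracy", "attack success"), lty = 1:2, bty = "n",
         cex = 0.8)
  plot(r$round, r$C_t, type = "l", log = "y", xlab = "round",
       ylab = expression(C[t]), main = "clipping threshold")
  plot(r$round, r$spent_epsilon, type = "l", xlab = "round",
       ylab = expression(epsilon), main = "privacy spend")
  abline(h = x$config$epsilon, lty = 3)
  plot(r$round, r$n_qualified, type = "l", xlab = "round",
       ylab = "count", ylim = c(0, x$config$K),
       main = "qualified updates / blacklist")
  lines(r$round, r$blacklist_size, lty = 2)
  invisible(x)
}
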