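#' @title Label-flipping poisoning harness
#'
#' @description
#' The adversary model is a static data-poisoning attack: before training
#' starts, a seeded draw designates `round(poisoned_fraction * K)` devices
#' whose shards have every label inverted (`y -> 1 - y`) while the
#' feature matrix stays byte-identical.  Optionally a set of verifiers can
#' be marked malicious (they endorse exactly the updates they should
#' reject and vote against valid blocks), exercising the
#' majority-signature and reputation defences; the protocol's security
#' assumption caps them below one third of the miners.
#'
#' @param K total number of devices.
#' @param poisoned_fraction fraction of devices poisoned, in \[0, 1\].
#' @param seed integer seed for the designation draw.
#' @param device_ids device identifiers (defaults to `1:K`).
#' @param malicious_verifier_ids optional ids of misbehaving verifiers.
#' @return `attack_config()` returns an object of class `attack_config`
#'   with the resolved `poisoned_device_ids`.
#' @examples
#' attack_config(20, 0.3, seed = 1)$poisoned_device_ids  # 6 devices
#' @export
attack_config <- function(K, poisoned_fraction = 0.3, seed = 1,
                          device_ids = NULL,
                          malicious_verifier_ids = character()) {
  if (poisoned_fraction < 0 || poisoned_fraction > 1)
    stop_param("'poisoned_fraction' must be in [0, 1]")
  device_ids <- device_ids %||% as.character(seq_len(K))
  stopifnot(length(device_ids) == K)
  n_poison <- round(poisoned_fraction * K)
  poisoned <- if (n_poison > 0)
    sort(with_seed(derive_seed(seed, "attack_designation", K,
                               poisoned_fraction),
                   sample(device_ids, n_poison)))
  else character()
  structure(list(poisoned_fraction = poisoned_fraction,
                 device_ids = device_ids,
                 poisoned_device_ids = poisoned,
                 malicious_verifier_ids = as.character(malicious_verifier_ids),
                 seed = seed),
            class = "attack_config")
}

#' @describeIn attack_config invert every binary label of a shard,
#'   keeping the features untouched.  Applying it twice restores the
#'   shard.
#' @param shard a `clinical_dataset`.
#' @export
flip_labels <- function(shard) {
  stopifnot(inherits(shard, "clinical_dataset"))
  if (length(shard$labels) && !all(shard$labels %in% c(0L, 1L)))
    stop_param("labels must be binary")
  shard$labels <- 1L - shard$labels
  shard
}

#' @describeIn attack_config replace the shards of the designated devices
#'   by their label-flipped versions.
#' @param partition a [partition_devices()] result; shard `k` belongs to
#'   device `device_ids[k]`.
#' @param cfg an `attack_config`.
#' @export
apply_attack <- function(partition, cfg) {
  stopifnot(inherits(partition, "device_partition"),
            inherits(cfg, "attack_config"))
  device_ids <- cfg$device_ids %||% as.character(seq_len(partition$K))
  for (k in seq_len(partition$K)) {
    if (device_ids[k] %in% cfg$poisoned_device_ids)
      partition$shards[[k]] <- flip_labels(partition$shards[[k]])
  }
  partition
}
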