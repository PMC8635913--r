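# fedchain

A desk-scale R simulator and library for **blockchain-coordinated federated
learning on clinical data** with adaptive differential privacy and
Byzantine-robust gradient verification.

Federated learning lets edge devices (wearables, bedside monitors) train a
shared diagnostic model without moving patient records, but a vanilla
deployment has three soft spots: a central aggregation server (single point
of failure), model updates that leak private information, and devices whose
data has been poisoned.  `fedchain` implements, end to end and fully
seeded, a protocol that addresses all three:

* **Ledger instead of server.**  Each training round is a block: SHA-256
  hash-chained, carrying the round's qualified updates with device and
  verifier signatures, committed only with a strict 2/3 committee
  supermajority (an empty block keeps the chain moving otherwise).
* **Adaptive differential privacy.**  Before upload, a device's per-round
  update g is released as
  `g / max(1, ||g||2 / C_t) + N(0, C_t^2 sigma^2 I)`, where the clipping
  threshold adapts to an exponential moving average of the global update's
  squared norm: `C_t = C` while `E[g~^2] <= G`, else
  `C_t = beta * sqrt(E[g~^2])`.  A moments accountant (log-moments
  `alpha(lambda) = log max(E1, E2)` of the subsampled Gaussian mechanism,
  additive composition, tail bound
  `epsilon = min_lambda (alpha(lambda) + log(1/delta)) / lambda`) tracks
  the spend and halts training at the budget.
* **Verification committee.**  Miners are drawn from a consistent-hashing
  ring with arcs proportional to reputation; the committee screens the
  update pool with multi-KRUM (score = sum of Euclidean distances to the
  `R - f - 2` nearest updates, keep the lowest `R - f`), endorses by
  majority signature, and reputations move +-1 per round with permanent
  blacklisting at zero.
* **Adversary harness.**  Static label-flipping on a configurable fraction
  of devices plus optional malicious verifiers; attack success rate
  (test-set misclassification) and per-round detection precision/recall
  are reported.

A seeded generator of Pima-like diabetes tables (eight integer predictors,
binary outcome, known logistic ground truth) makes everything testable
offline; an optional loader accepts any CSV with the nine-column schema.

## Worked example

```r
library(fedchain)

cfg <- fedchain_config(n = 768, T_max = 12, sigma = 0,
                       check_budget = FALSE,
                       poisoned_fraction = 0.3, krum_f = 6, seed = 1)
fit <- fedchain(cfg)
fit
#> Blockchain-coordinated federated learning run
#>   rounds: 12 (max_rounds)   devices: 20   backend: logistic
#>   final accuracy: 0.865   attack success rate: 0.135
#>   spent epsilon: 0.000 (delta = 0.0001)   blacklist: 4
```

Twenty devices share 538 training rows (70% of 768); six of them train on
fully label-flipped shards.  With the noise multiplier at 0 the defended
model reaches 86.5% test accuracy — an attack success rate of 13.5% — and
four devices have been blacklisted by round 12.  The fitted object behaves
like a classical model fit:

```r
round(coef(fit), 3)
#>                Pregnanci                  Glucose            BloodPressure
#>                    0.197                    0.671                    0.019
#>            SkinThickness                  Insulin                      BMI
#>                    0.028                    0.018                    0.446
#> DiabetesPedigreeFunction                      Age                   (bias)
#>                    0.257                    0.332                   -0.622

predict(fit, type = "prob")[1:5]   # class-1 probabilities on the test set
plot(fit)                          # accuracy/ASR, C_t, epsilon, blacklist
audit_chain(fit$chain, fit$keys)   # re-verify the whole ledger
```

The privacy accountant can be queried standalone; with the default
hyperparameters (`C = 3`, `sigma = 4`, so a noise sd of 12 against unit
shift, `q = 1`) and 20 devices:

```r
led <- accumulate_moments(moment_ledger(),
                          mechanism_spec(q = 1, noise_std = 12),
                          devices = 20, rounds = 36)
epsilon_for_delta(led, 1e-4)
#> [1] 12.10517
```

A thin command line lives in `inst/cli/fedchain`
(`simulate`, `audit`, `accountant`, `gen-data`), e.g.

```sh
Rscript inst/cli/fedchain simulate --config cfg.yaml --out-dir run1
Rscript inst/cli/fedchain audit --chain run1/chain --seed 3
```

Two caveats worth knowing before interpreting output at the published
hyperparameters — both dynamics of the method as specified, documented
with their mechanism in the methods vignette
(`vignettes/fedchain-methods.Rmd`): at `sigma = 4` the per-coordinate
noise sd `C_t * sigma` dominates small tabular models, and the adaptive
threshold then *grows* geometrically instead of decaying; and after the
first round the threshold collapse clips every update onto the same
sphere, where coordinated flipped updates form a tighter cluster than
honest ones and multi-KRUM's outlier assumption breaks.

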