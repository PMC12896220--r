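# glnet

Depression among students is common (prevalence around 59% in large
self-report surveys) and shaped by many interacting factors — academic
pressure, sleep, diet, financial stress, family history, suicidal
ideation. `glnet` is an R package for modelling student depression risk
from such mixed-type survey records and, just as importantly, for
*explaining* the fitted model: which factors drive the predicted risk,
with what sign, and how that differs between subgroups (female vs male
students, undergraduates vs doctoral students). It is aimed at
biostatisticians and mental-health researchers who want an end-to-end,
reproducible tabular deep-learning workflow without leaving R.

## The model

The classifier is a **global-local state-space network**: encoded survey
factors x are embedded by a linear layer into 128 deep features
(`x_fc = f_fc(x)`), which four *Global-and-Local Blocks* (GLBs) process as
a feature sequence. Each block composes

```
f_glb(x) = BN( f_fc( beta( f_conv( f_mamba(x) ) ) ) )
```

where `f_mamba` is a selective state-space scan — a Mamba-style layer
with state `h_t = exp(Delta_t A) h_{t-1} + Delta_t B_t x_t`, output
`y_t = <C_t, h_t> + D x_t`, and input-dependent `Delta_t, B_t, C_t` —
capturing long-range (global) structure across the feature sequence in
linear time; `f_conv` is a kernel-3 1-D convolution for local structure;
`beta` is a leaky-ReLU; `f_fc` doubles the width in the first two blocks
and halves it in the last two; `BN` is batch normalization. A residual
connection joins the equal-width shallow and deep features
(`y = f_glb_down(f_glb_down(f_glb_up(x_glb1)) + x_glb1)`) in a U-shaped
residual layout, and a linear head with softmax yields the depression
probability.

Training uses class-weighted cross-entropy (inverse-frequency weights
`w_c = n/(2 n_c)` against the 59/41 label imbalance), the Ranger
optimizer (RAdam + Lookahead) at an initial learning rate of 1e-4 with
cosine decay, batch size 256, and 10% factor-dropout plus ±0.1
standardized-scale jitter as augmentation. Evaluation reports AUC,
accuracy, sensitivity, specificity and F1 with percentile-bootstrap 95%
confidence intervals.

Factor contributions are **Shapley values** of the predicted probability,

```
phi_i = sum over S ⊆ N\{i} of |S|!(|N|-|S|-1)!/|N|! [f(S ∪ {i}) - f(S)]
```

with the interventional (background-masked) value function, computed by
exact enumeration for small factor sets and batched permutation sampling
at full scale, then summarized globally (mean |phi| rankings, beeswarm
exports) and per subgroup. The gradients of the whole network are derived
by hand and checked against finite differences; the state-space scan runs
in compiled code (RcppArmadillo).

Because the real survey data cannot ship with the package, a synthetic
generator produces records from the same schema with a known logistic
ground truth — including planted CGPA-by-gender and diet-by-degree
interactions — so the entire pipeline is testable end-to-end by recovery
of planted structure.

## Worked example

Simulate a 3,000-student survey, run the full pipeline (encode, split,
standardize, train, evaluate, attribute, summarize), and inspect it:

```r
library(glnet)

sim <- pipeline_simulate("default", n = 3000, seed = 42, out = "students")
cfg <- run_config(
  input_csv = sim["csv"], out_dir = "students_run", seed = 42,
  model = list(embed_dim = 32),
  train = list(epochs = 250, early_stop_patience = 250),
  attribution = list(n_explain = 80, M = 10, background = 30),
  subgroups = c("Gender=Female", "Gender=Male"))
res <- pipeline_run_all(cfg)

print(res$report)
#> <metrics_report> n = 600  threshold = 0.5
#>   AUC   81.48%  (95% CI 78.15-84.80)
#>   ACC   73.00%  (95% CI 69.50-76.34)
#>   SEN   72.42%  (95% CI 67.80-76.80)
#>   SPE   73.86%  (95% CI 68.49-79.33)
#>   F1    76.25%  (95% CI 72.62-79.55)

head(res$summary$ranking[, c("column", "mean_abs_phi", "mean_phi")], 6)
#>                             column mean_abs_phi    mean_phi
#> 1            Suicidal Thoughts=Yes   0.11322754 -0.02196697
#> 2             Suicidal Thoughts=No   0.08811434 -0.02235086
#> 3                Academic Pressure   0.07481542 -0.04954131
#> 4                 Work/Study Hours   0.05330392  0.01610638
#> 5 Sleep Duration=More than 8 hours   0.05075756  0.02424327
#> 6                 Financial Stress   0.05038734  0.01716361
```

The report gives test-set discrimination with bootstrap CIs: here the
network separates depressed from non-depressed students with AUC ~81%
(the generator's own Bayes-optimal AUC at this signal strength is ~93%,
approached more closely at larger n and longer schedules). The ranking
lists encoded factor columns by mean absolute Shapley value: suicidal
ideation dominates, followed by academic pressure and work/study hours —
the structure the generator planted. Positive per-sample `phi` pushes a
prediction toward the depressed class; `res$summary$beeswarm` holds the
(sample, column, phi, value) triples behind a beeswarm plot, and the run
directory contains every artifact (schema, split, standardizer,
checkpoint, metrics, attributions, subgroup summaries) plus a
content-hash manifest. Subgroup summaries expose the planted
interactions, e.g. a positive CGPA phi-vs-value slope among female
students only.

A thin command-line wrapper covers the same workflow:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/glnet.R", package="glnet"))') \
    simulate --n 3000 --seed 42 --out students
```

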