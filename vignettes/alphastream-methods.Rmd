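---
title: "Online error rate control with alphastream: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Online error rate control with alphastream}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alphastream)
```

## The problem

In A/B testing programmes, platform trials and growing data repositories,
hypotheses are not tested all at once: p-values $P_1, P_2, \dots$ arrive one
at a time and each decision must be made immediately, using only the current
p-value and the record of past rejections — never the total number of tests,
which may be unknown or unbounded. A procedure in this setting emits a test
level $\alpha_t$ before seeing $P_t$ and rejects iff $P_t \le \alpha_t$
(ties reject). The goal is to control an error rate — usually the false
discovery rate $\mathrm{FDR}(T) = E[V(T)/(R(T)\vee 1)]$, sometimes the
familywise error rate — at a preset level $\alpha$ *at every time* $T$.

`alphastream` implements the generalized alpha-investing (GAI) family of
online procedures. Testing costs alpha-wealth ($\phi_t$), a rejection earns
some back ($\psi_t$), and the ledger
$W(t) = W(t-1) - \phi_t + R_t\psi_t$ must stay non-negative. The GAI++
refinement caps the payout at
$\min\{\phi_t + b_t,\ \phi_t/\alpha_t + b_t - 1\}$ with
$b_t = \alpha - w_0 1\{R(t-1)=0\}$, which is what upgrades marginal-FDR
control to FDR control for monotone rules under independent nulls. The
equivalent "statistical" view, which the implementations follow, is to keep
an empirical FDP estimate below $\alpha$ at all times:
$\widehat{\mathrm{FDP}}(t) = \sum_{j\le t}\alpha_j / (R(t)\vee 1)$ for
LORD-type rules, and
$\sum_{j\le t}\alpha_j 1\{P_j > \lambda\}/(1-\lambda)\,/(R(t)\vee1)$ for the
adaptive rules. Both views are recorded per step: every decision log carries
$(\alpha_t, \phi_t, \psi_t, R_t, W(t))$, so the wealth trajectory is
auditable after the fact.

## The algorithms

All wealth-earning policies distribute each budget source (the initial
wealth $w_0$ and each rejection's reward) over future tests according to a
*spending sequence* $\{\gamma_t\}$: non-negative, non-increasing weights
summing to one.

* **Alpha-spending** ($\alpha_t = \alpha\gamma_t$) and **online Šidák**
  ($\alpha_t = 1-(1-\alpha)^{\gamma_t}$) control the FWER; they never earn
  wealth. The Šidák level dominates the spending level pointwise because
  $1-(1-\alpha)^{\gamma} \ge \alpha\gamma$ on $\gamma \in [0,1]$.
* **LORD** pays $b_0$ per rejection:
  $\alpha_t = w_0\gamma_t + b_0\sum_{j:\tau_j<t}\gamma_{t-\tau_j}$, with
  $w_0 + b_0 \le \alpha$.
* **LORD++** pays $\alpha-w_0$ for the first rejection and $\alpha$
  thereafter:
  $\alpha_t = w_0\gamma_t + (\alpha-w_0)\gamma_{t-\tau_1} +
  \alpha\sum_{j\ge2:\tau_j<t}\gamma_{t-\tau_j}$.
* **SAFFRON** never spends on *candidate* p-values ($P_t \le \lambda$) and
  caps its levels at $\lambda$; the spending-sequence index for each budget
  source advances only at non-candidate steps, which is what the shifted
  indices $t - \tau_j - C_{j+}$ implement ($C_{j+}$ counts candidates
  strictly between $\tau_j$ and $t$). The bracket is scaled by $1-\lambda$.
* **ADDIS** additionally *discards* p-values above $\eta$: a discarded
  p-value changes nothing downstream, exactly as if it had never arrived
  (property-tested). Its sequence is indexed from 0 and advances only at
  selected steps; the scale factor is $\eta-\lambda$ and the initial wealth
  $(\eta-\lambda)w_0$. Discarding pays off when nulls are *conservative*
  (stochastically larger than uniform). With $\eta = 1$ ADDIS reduces
  exactly to SAFFRON, which the package permits and tests.
* **Monotone alpha-investing** is under-specified in the source literature
  beyond $\alpha_t = \phi_t/(1+\phi_t)$. We implement it as the SAFFRON
  recursion with *self-candidacy*: the candidacy threshold at step $j$ is
  $\alpha_j$ itself, and the $(1-\lambda)$ discount becomes $(1-\alpha_t)$,
  so the level solves $\alpha_t = (1-\alpha_t)b_t$, i.e.
  $\alpha_t = b_t/(1+b_t)$ in closed form (no iteration). This construction
  is monotone and wealth-safe by the same argument as SAFFRON; because the
  exact schedule is a design choice, the rule is excluded from the golden
  case-study checks and is validated by property tests only (fixed-point,
  monotonicity, wealth non-negativity, oracle equivalence).

Every recursion is implemented once in C++ (single pass, shifted-index
bookkeeping) and once, independently, as a quadratic closed-form
re-evaluation in the test suite; the two agree to $10^{-12}$ on random
streams.

## Spending sequences and numerical choices

Three schedules are provided (`spending_sequence()`):

| kind | weight | default use |
|---|---|---|
| `lord-default` | $\gamma_t \propto \log(t\vee2)/(t e^{\sqrt{\log t}})$ | LORD/LORD++, alpha-spending |
| `power` | $\gamma_t \propto t^{-s}$ (or $(j+1)^{-s}$ from $j=0$) | SAFFRON ($s=1.6$), ADDIS |
| `uniform` | $1/M$ up to a finite bound | Bonferroni-style bounded runs |

**Bounded variants.** With an a-priori horizon $M$, weights past $M$ are
zero and the retained weights are *renormalized* to sum to one — not merely
truncated. Renormalization is the convention that reproduces the published
platform-trial levels (e.g. bounded SAFFRON's next level 0.0165), and it
concentrates the whole budget inside the horizon, which is where the power
gain of bounded rules comes from.

**Infinite-horizon normalization.** $\sum_t t^{-s}$ and the default LORD
series are computed by direct summation to a cutoff plus an analytic tail:
for the default sequence the substitution $u=\sqrt{\log t}$ gives
$\int_N^\infty \!\gamma \propto 2e^{-U}(U^3+3U^2+6U+6)$, to which
Euler–Maclaurin corrections are added. The resulting constant,
$\sum_t u_t = 12.6451078728718$, is cutoff-independent to $10^{-12}$ across
cutoffs $10^4$–$10^8$ and was confirmed against a 30-digit arbitrary
precision oracle. A constant widely circulated in earlier software
($0.07720838$, i.e. a sum of $12.952$) is inconsistent with the formula; we
use the computed value. This choice only affects unbounded runs, and any
valid normalization preserves the control guarantees (the sequence still
sums to at most one).

**Degenerate inputs.** p-values exactly 0 or 1 are legal; ties at the level
reject; the GAI++ payout cap clamps negative caps at zero and flags them;
empty streams produce an empty log whose "next level" is the first-step
level; levels past a finite bound are exactly zero.

## Default parameters

| parameter | default | rationale |
|---|---|---|
| $\alpha$ | 0.05 | conventional target level |
| $w_0$ (LORD++) | $\alpha/10$ | reproduces the published platform-trial level 0.0002 |
| $w_0$ (SAFFRON/ADDIS/AI) | $\alpha/2$ | reproduces the published levels 0.0165 / 0.0016 |
| $\lambda$ (SAFFRON) | 0.5 | standard default; candidate threshold |
| $\lambda,\eta$ (ADDIS) | 0.25, 0.5 | standard defaults; $\lambda<\eta$ required |
| $s$ (power-law) | 1.6 | exponent found to work well empirically in the source literature |

The initial-wealth defaults deserve a note: the source literature states no
$w_0$ defaults, but only $w_0=\alpha/10$ (LORD++) and $w_0=\alpha/2$
(SAFFRON/ADDIS) are consistent with the published case-study levels, which
we verified by hand-tracing the recursions before freezing the defaults.

## The simulation testbed

`generate_stream()` draws $Z_t \sim N(\mu_t, 1)$ with
$\mu_t \sim (1-\pi_1) F_0 + \pi_1 F_1$, $F_1 = N(3,1)$, and emits one-sided
p-values $P_t = \Phi(-Z_t)$; the truth label is the mixture component. Two
null laws are provided: a point mass at 0 (exactly uniform nulls) and
$F_0 = N(-0.5, \texttt{null\_sd}^2)$, which makes essentially every null
conservative — the regime where discarding pays.

**What the fixed defaults represent.** $T = 1000$, $\alpha = 0.05$,
$F_1 = N(3,1)$ and $\pi_1$ grids over $\{0.01,\dots,0.9\}$ mirror the
published experimental design. The published notation "$N(-0.5, 0.1)$" does
not say whether $0.1$ is a variance or a standard deviation; we checked the
design's headline number under both (uncorrected FDR at $\pi_1=0.01$:
$0.662 \pm 0.001$ with $\mathrm{sd}=0.1$, $0.709 \pm 0.001$ with variance
$0.1$) and adopted $\mathrm{sd}=0.1$, the reading consistent with the
published value of roughly $0.65$; `null_sd` is the switch between the two.
Note the residual gap: the computed value under the stated design is
$0.662$, stable across seeds, replicate counts and labeling conventions,
while the published figure-read value is $0.65$. Our acceptance test checks
the strict 3-standard-error band against $0.65$ and therefore fails by a
small margin; we keep that check faithful rather than widen it, and report
the computed value.

**Replicates and seeds.** The published curves use $10^4$ replicates; the
in-suite runs are scaled down to $2000$ (tolerance three Monte-Carlo
standard errors, gaps resolved at two), which keeps the whole suite around
half a minute. A master seed spawns one substream seed per replicate, so any
replicate is reproducible in isolation, and streams are shared across
algorithms within a replicate so algorithm contrasts are paired.

**What a green test does not establish.** The testbed draws independent
hypotheses. It says nothing about correlated p-values (shared control arms,
overlapping repository data), asynchronous or batched arrivals, composite
non-Gaussian tests, or adversarial orderings — all of which are out of scope
here. FDR control by these algorithms is proven under independent nulls;
the simulations probe that regime only.

## Error-rate estimators

Per-replicate FDP and power use floored denominators ($R\vee1$,
$|\mathcal{H}_1|\vee1$), so empty runs contribute zero rather than NaN. The
FDR estimate is the mean FDP with standard error
$\mathrm{sd}/\sqrt{n}$; the marginal FDR is the *ratio of means*
$E[V]/E[R\vee1]$ exactly (delta-method standard error); FDX$(\epsilon)$
uses the running supremum of the FDP; FWER and FDX report binomial standard
errors $\sqrt{p(1-p)/n}$, which gives exactly $0.005$ for a proportion of
$0.5$ at $10^4$ replicates.

## Known limitations

* FDR guarantees require independent null p-values; only empirical evidence
  (elsewhere) supports robustness to positive dependence.
* LOND, supLORD, online fallback, ADDIS-spending, weighted/decaying-memory
  and asynchronous variants are deliberately not implemented.
* The monotone alpha-investing schedule is this package's construction of
  an under-specified rule; compare levels across implementations before
  relying on exact values.
* Batch labels in input files are provenance only; the run order is the
  file's row order.

## Reproducing the case study

```{r stampede}
st <- stampede_fixture()
log <- run_stream(st$pval, saffron(alpha = 0.05, bound = 20), ids = st$id)
log
```

`scripts/acceptance.R --seed 1 --out results/acceptance.json` (from the
repository root, against the installed package) recomputes the four
acceptance targets — the three bounded next-hypothesis levels above and the
uncorrected-testing FDR — from scratch.
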