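---
title: "Methods: Gibbs sampling for the extended marginal Rasch model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Gibbs sampling for the extended marginal Rasch model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

The marginal Rasch model integrates the one-parameter logistic IRT model
over an ability density $f$:

$$P(\mathbf x) \;=\; \int \prod_i
  \frac{\exp\{x_i(\theta-\delta_i)\}}{1+\exp(\theta-\delta_i)}\,
  f(\theta)\,d\theta .$$

Writing $b_i=e^{-\delta_i}$ (easiness) and
$\lambda_s = E[e^{s\Theta}\mid \mathbf X=\mathbf 0]$ (the moments of the
all-incorrect posterior of ability), the manifest distribution can be put
in the Cressie–Holland / Tjur form

$$P(\mathbf x \mid \mathbf b, \boldsymbol\lambda)
  = \frac{\prod_i b_i^{x_i}\,\lambda_{x_+}}
         {\sum_{s=0}^n \gamma_s(\mathbf b)\,\lambda_s},$$

where $x_+$ is the sum score and $\gamma_s$ is the elementary symmetric
function (ESF) of order $s$.  Taken as a model for *any* non-negative
$\lambda$, this is the **extended** marginal Rasch model: a proper
manifest probability model that involves no latent variable at all.  Three
consequences drive the package design:

* the sufficient statistics are the item totals $x_{+i}$, the score
  counts $m_s$ and the respondent count $m$ — nothing else;
* the conditional-likelihood factorization makes Bayesian inference here
  the analogue of conditional maximum likelihood (CML) estimation;
* by the Dutch identity, $\tau_s=\lambda_{s+1}/\lambda_s =
  E[e^{\Theta}\mid X_+=s]$: EAP ability estimators are *parameters* of
  the manifest model, even though individual abilities are not.

The posterior under independent power priors
$b_i^{\alpha_i-1}$, $\lambda_s^{\beta_s-1}$ is

$$f(\mathbf b,\boldsymbol\lambda\mid\text{data}) \propto
  \frac{\prod_i b_i^{x_{+i}+\alpha_i-1}\,
        \prod_s \lambda_s^{m_s+\beta_s-1}}
       {\bigl(\sum_s \gamma_s(\mathbf b)\lambda_s\bigr)^m}.$$

Because the normalizer is *linear* in every single parameter (via the ESF
recursion $\gamma_s(\mathbf b)=\gamma_s(\mathbf b^{(i)})+
b_i\gamma_{s-1}(\mathbf b^{(i)})$), every full conditional has the form
$v^{k-1}/(1+cv)^{M}$ — a **scaled Beta prime** distribution, sampled
exactly through $y=cv/(1+cv)\sim\mathrm{Beta}(k,\,M-k)$.  No data
augmentation is involved, and one sweep costs $O(n^2)$ regardless of $m$.

## Numerical choices

* **ESFs in log space.**  All ESFs are computed by the one-item-at-a-time
  recursion carried out entirely in logs (compiled kernel), so nothing can
  overflow even for several hundred items; the property suite checks
  finiteness at $n=300$ with easiness spanning $e^{\pm4}$.  ESFs with an
  item removed are recomputed from scratch; downdating the recursion is
  numerically unstable (catastrophic cancellation), and the resulting
  quadratic sweep cost matches the algorithm's known complexity.
* **Out-of-range ESF indices** ($s<0$ or $s>n$) are defined as 0
  ($-\infty$ in logs), which makes the recursion and the conditional-scale
  sums well defined at the boundaries.
* **Truncated draws** (for the order-constrained sampler) use the
  inverse-CDF on the Beta scale restricted to the mapped interval, with a
  survival-scale fallback when both bounds sit in the far upper tail and a
  midpoint fallback when the interval is numerically a point mass.
* **Quadrature oracles** (used for ground truth, never inside the
  sampler) integrate on a fixed trapezoid grid over $\theta\in[-8,8]$ with
  801 nodes; for smooth, rapidly decaying integrands the trapezoid rule is
  spectrally accurate there, far below every tolerance the tests use.

## Identification: the one genuinely delicate point

The likelihood is invariant under
$(\mathbf b,\boldsymbol\lambda)\to(c\mathbf b,\lambda_s/c^s)$ and under a
common rescaling of $\boldsymbol\lambda$; the conventional constraints are
$b_{\text{ref}}=1$ and $\lambda_0=1$.  Two facts, established empirically
by this package's own test suite and easy to verify analytically, shape
the implementation:

1. **Under the flat prior the *unconstrained* posterior is improper.**
   Along the ray $\boldsymbol\lambda\to a\boldsymbol\lambda$ the density
   is exactly constant, because $\sum_s m_s=m$ makes the numerator and
   denominator powers of $a$ cancel.  An improper measure has no canonical
   marginal for the identified quantities, so "sample everything and
   normalize afterwards" has no unique Bayesian target.
2. **The two natural schemes behave very differently.**
   *Fixing* $b_{\text{ref}}$ and $\lambda_0$ (never sampling them) targets
   the proper identified posterior exactly — the package validates this
   against two independent oracles (a correlated-proposal importance
   sampler and a random-walk Metropolis sampler, both driven only by the
   posterior density with brute-force ESFs).  But the resulting chain
   mixes very slowly: the overall profile of $\boldsymbol\lambda$ must
   equilibrate through local moves, and the lag-1 autocorrelation of an
   item parameter approaches 0.9 at the canonical design.
   *Updating every parameter* and applying the likelihood-invariant
   rescaling after each sweep (the sweep kernel is equivariant under the
   invariance group, so rescaling inside the chain changes nothing about
   the law of identified draws) restores the fast mixing this sampler is
   known for — successive-iteration ECDFs coincide within a few dozen
   iterations and autocorrelation beyond lag 1 is negligible — because
   the free gauge direction acts like parameter expansion.  Its identified
   draws are *not* exactly the identified posterior, but the difference is
   $O(1/m)$: invisible at survey scale ($m=10^5$), and detectable only in
   deliberately tiny datasets (tens of respondents), which is where the
   test suite pins it down.

`chain_config(identification = )` exposes both: `"rescale"` (default;
fast-mixing, the scheme whose operating characteristics the replicated
chain study exhibits) and `"fixed"` (exact identified posterior; use it
for small-sample inference or oracle validation, with longer chains).
The NEAT and polytomous samplers use the fixed scheme; their tests run
longer chains to compensate.

Relatedly, propriety of the full conditionals requires
$0 < x_{+i}+\alpha_i < m$ and $0 < m_s+\beta_s < m$; `gibbs_run` enforces
exactly these.  "Every score occurs at least once" is *sufficient* but not
necessary under the flat prior (an absent score leaves a proper
Beta$(1, m-1)$-type conditional), so an absent score does not abort a run;
an item answered correctly by all but one respondent, perhaps
surprisingly, does ($k=m$).

## The monotone-$\tau$ constraint

The extended model is a genuine *marginal* Rasch model only if
$\boldsymbol\lambda$ is a moment sequence.  The package implements the
pairwise consequence used in practice:
$\lambda_{s+2}\lambda_s \ge \lambda_{s+1}^2$ (log-convexity), equivalently
$\tau_s$ non-decreasing — non-negative posterior ability variance at every
score, the minimal requirement for educational measurement.  In the Gibbs
sweep this becomes a double truncation
$\max(\lambda_{t-1}^2/\lambda_{t-2},\,\lambda_{t+1}^2/\lambda_{t+2})
\le \lambda_t \le \sqrt{\lambda_{t-1}\lambda_{t+1}}$, dropping the terms
whose neighbours fall outside $0..n$.  A strictly geometric starting
$\lambda$ satisfies every constraint *with equality*, which collapses all
truncation intervals to points and freezes the chain; constrained runs
therefore start from a strictly log-convex sequence
($\tau_s = u\cdot1.25^s$, $u\sim U(0,1)$).  The full Shohat–Tamarkin
moment determinant system and Bayes-factor tests of the constraint set are
out of scope.

## Ability summaries

For score $s$, per retained draw, $E[e^\Theta\mid X_+=s]=
\lambda_{s+1}/\lambda_s$ and $V[e^\Theta\mid X_+=s]=
\lambda_{s+2}/\lambda_s - (\lambda_{s+1}/\lambda_s)^2$; aggregation over
draws is done on these functionals (never on averaged $\lambda$'s),
splitting total posterior variance into a parameter-uncertainty part
(vanishes as $m\to\infty$; the test suite checks the monotone decrease
over $m=10^2,10^4,10^6$) and a finite-test-length part (vanishes as
$n\to\infty$).  The mean exists for $s\le n-1$ (a perfect score has no
estimable EAP) and the variance for $s\le n-2$.  The $\theta$-scale
summaries $\mu_s = 2\ln E_1 - \tfrac12\ln E_2$ and
$\sigma^2_s = \ln E_2 - 2\ln E_1$ come from matching log-normal moments
and are reported as *approximations only* (flagged in the output): no
criterion for the adequacy of posterior normality is imposed, and with
unconstrained draws the empirical moments can even be inconsistent
($E_2<E_1^2$), in which case the row is left `NA`.

## Incomplete (NEAT) designs

With two groups sharing an anchor, unique items and the per-group score
parameters keep their conjugate updates (restricted to their own group's
normalizer).  An anchor item appears in *two* normalizers, so its
conditional is $b^{k-1}/[(1+a_1b)^{m_{xy}}(1+a_2b)^{m_{xz}}]$ — log-concave
with linear tails on the difficulty scale.  Rather than adaptive rejection
sampling, a Metropolis step is used whose proposal is the complete-design
conditional shape with its scale solved in closed form so that the
log-density slopes match at the current state; when $a_1=a_2$ the proposal
*is* the target and every proposal is accepted, and with one group empty
the sampler reduces exactly to the complete design (both reductions are
tested, including distributional agreement of the Metropolis route with
the conjugate route on the same posterior).  One proposal per anchor per
sweep; acceptance rates are recorded.  Identification fixes one anchor at
easiness 1 plus $\lambda_0=\eta_0=1$, extending the complete-design rule
per booklet.  A degenerate slope match ($q\in\{0,1\}$, possible only in
pathological states) keeps the current value with a warning.

## Polytomous items with fixed integer weights

For nominal-response items whose integer category weights $a_{ij}$ are
known, the weighted total $y_{++}$ is sufficient for ability and the same
manifest representation holds with generalized ESFs over category
patterns, computed by the corresponding recursion on the achievable-score
lattice (a subset-sum set; $\lambda$ exists only there).  The normalizer
is again linear in each category easiness $b_{ij}$, with the linearization
coefficient $\sum_s \gamma_{s-a_{ij}}(\text{bank}^{(i)})\lambda_s$, so
every update is the same scaled-Beta-prime primitive; with all $J_i=1$ and
unit weights the statistics, the ESFs and the draws all reduce exactly to
the dichotomous ones (tested, including bitwise equality of draws under a
shared RNG state).  Estimating the weights is out of scope — they are part
of the scoring rule.

## Synthetic data

Two generation routes, which the tests verify agree in law:

* `simulate_latent_rasch`: ability draws from a pluggable distribution
  (default standard normal, the canonical design: 30 items, difficulties
  uniform on $(-2,2)$, $10^5$ respondents), responses Bernoulli-logistic.
* `simulate_extended`: score from the manifest score distribution, then
  the pattern given the score by the sequential conditional rule — exact
  for any valid $(\mathbf b, \boldsymbol\lambda)$, no latent variable.

The generator emulates unidimensional, locally independent,
equal-discrimination data with a smooth population density.  It does not
emulate guessing, discrimination variation, local dependence, or missing
data outside the NEAT structure — so a green recovery test establishes
correctness of the *sampler*, not robustness of the Rasch model to
misspecification (the item-rest fit diagnostic, conversely, is shown to
flag injected guessing).

## Diagnostics

Convergence is operationalized as non-rejection of a two-sample KS test
between cross-replication samples of a parameter at successive iterations
($\alpha=0.05$); "negligible" autocorrelation as $|r|\le0.1$ (both
thresholds configurable — the original presentation is visual).  The
item-rest regression $P(X_i=1\mid\text{rest}=r)=
b_i\tau_r/(1+b_i\tau_r)$ uses the full-model ratio
$\tau_r=\lambda_{r+1}/\lambda_r$ (this follows from direct
marginalization of the pattern probabilities); the per-item discrepancy is
the count-share-weighted maximum absolute difference between observed and
posterior-mean curves, calibrated against posterior-predictive
replicates.  Wall-clock comparisons are excluded by design: the
person-independence of the per-iteration cost is structural (the sampler
consumes only sufficient statistics).

## Known limitations

* The default chain's identified draws carry an $O(1/m)$ gauge effect
  (see above); for very small samples use `identification = "fixed"` with
  long chains, or informative priors.
* The multidimensional two-test model and log-polynomial smoothing of
  $\boldsymbol\lambda$ are not implemented.
* The monotone-$\tau$ constraint is the only moment constraint enforced;
  it is necessary, not sufficient, for $\boldsymbol\lambda$ to be a true
  moment sequence.
* The normal-scale ability summaries are heuristic approximations with no
  adequacy check.
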