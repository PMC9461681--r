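---
title: "Methods: from roster surveys to network measures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from roster surveys to network measures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orgnet)
```

## The problem orgnet addresses

Whole-network ("sociometric") studies of interorganizational collaboration
survey every organization on a fixed roster about its relationships with
every other organization on that roster. In integrated-care settings — for
example a geographic care-coordination network led by a lead agency — the
instrument typically asks about several relation types at once: how often
two organizations are in contact, how integrated each perceives the
relationship to be, and whether referrals, information, joint care plans
and resources flow between them. The raw material is therefore a stack of
*dyadic reports*: one organization's claim about one pair, under one
relation. Turning those claims into analyzable binary networks requires a
sequence of small, consequential preprocessing decisions, and `orgnet`
implements that sequence as a tested, configurable pipeline.

## Data model

Three tables drive everything:

* **Roster** — the bounded actor set: `org_id`, `name`, `org_type`,
  `is_lead` (exactly one lead agency), `responded`. Row order is frozen and
  defines sociomatrix indexing.
* **Dyadic responses** — long format: `reporter, source, target, relation,
  value`, with the reporter required to be an endpoint of the pair. For
  undirected relations the pair is canonicalized to lexicographic order so
  reports about (B, A) and (A, B) share one dyad key.
* **CPAT item responses** — `provider_id, item_id (1..56), value (1..7)`
  for the lead agency's interprofessional team.

A respondent who lists no value for some partner is treated as reporting
*no tie* (contact `none`, integration `not_linked`, binary 0) for that
partner. This roster-based questionnaire semantic is what makes
"respondent who reported nothing" distinguishable from "organization that
never answered the survey", which the imputation step depends on.

## Tie construction

Per relation, `build_network()` applies:

1. **Dichotomization.** Contact is linked at *monthly or more often* —
   contact more than twice per year; the biannual level itself is below
   the cut. Perceived integration is linked at *coordination or above*
   (codes 3–6 on the 7-level scale). Both cut-offs are configurable
   through `tie_rule_config()`.
2. **Mean-tie discrepancy resolution** (undirected). When both endpoints
   responded but disagree, the dyad takes the mean of the two dichotomized
   reports and is linked when that mean reaches the discrepancy threshold
   (default 0.5, so a (1, 0) split counts as linked). The averaging rule is
   stated in dichotomized terms, which is why dichotomize-first is the
   default order; averaging the raw ordinal codes before applying the
   cut-off is available as `discrepancy_order = "average_ordinal_first"`
   since the two readings genuinely differ (monthly + annually averages to
   a code below the coordination-style cut but to 0.5 after
   dichotomization).
3. **Reconstruction imputation** (undirected). A dyad with exactly one
   respondent endpoint takes that single respondent's report as the tie
   value. The rule is only defensible while organization-level nonresponse
   stays under the 30% limit; at or above it `build_network()` refuses with
   an instructive error rather than producing a silently fragile network.
   Dyads with *two* nonrespondent endpoints carry no information: they stay
   untied, are flagged in the missing mask, and raise a warning.
4. **Confirmed ties** (directed). An arc A→B is *confirmed* when A reports
   sending to B and B reports receiving from A; *unconfirmed* mode keeps
   arcs either endpoint reported. Confirmed mode cannot exist for dyads
   touching a nonrespondent, so by default those dyads fall back to the
   single available report and are flagged (`single_report_fallback =
   TRUE`); a strict mode drops them into the missing mask instead.
   Reconstruction proper is applied only to undirected relations; the
   fallback rule covers the directed case.

These choices give the pipeline two useful invariants, both under test:
the confirmed arc set is always a subset of the unconfirmed set, and
imputation never alters a dyad both of whose endpoints responded.

## Network measures and bands

For a network of `n` organizations with `L` ties:

* **Density** = `L / (n(n-1))` over ordered pairs for directed networks
  (equivalently `2E / (n(n-1))` undirected). The arc-level denominator is
  the convention of the standard sociometric toolchain; a dyad-level
  alternative (either arc links the pair) is available via
  `network_density(m, "dyad")`.
* **Degree centrality** — row/column sums; on directed input the total
  basis counts *distinct neighbours* (union of in- and out-ties), so an
  organization reciprocally tied to one partner has total degree 1, not 2.
* **Freeman degree centralization** — `sum(c_max - c_i)` normalized by its
  maximum attainable value: `(n-1)(n-2)` for undirected total degree and
  `(n-1)^2` for directed in-/out-degree (the standard Freeman extension;
  a star attains exactly 1 on the relevant basis, any regular network 0,
  and an all-zero network is 0 by the same arithmetic). The default basis
  is in-degree for directed networks, matching the node-sizing convention
  of the plots.
* **Bands** — density and centralization under 0.30 are *low*, 0.30–0.50
  inclusive *moderate*, above 0.50 *high*. Both boundary values classify
  as moderate.
* Metrics are carried at full precision; reports round densities and
  centralizations to 3 decimals and percentages (response rates,
  perception endorsements) to 1 decimal.

## CPAT scoring

The Collaborative Practice Assessment Tool has 56 items in 8 domains; each
domain is scored as the mean of its items, a provider's total is the sum
of the 8 domain means, and the team score is the unweighted mean of
provider totals. The printed bounds (8 and 56) force a 1–7 item scale
under this scoring, which the validators enforce. The published
instrument's uneven domain sizes are not in the public record used here,
so `cpat_domain_map()` accepts any 8-way disjoint partition of items 1..56
and ships a uniform 7-items-per-domain fallback; every bound and linearity
property holds for any valid map. Team aggregation as an unweighted mean
is itself an assumption — the instrument's documentation says only
"aggregated" — and is the simplest choice consistent with the bounds.

## The synthetic-case generator

No raw sociomatrices from roster studies of this kind are generally
public, so the package carries a first-class generator
(`simulation_config()`, `simulate_case()`) whose output feeds the same
readers and builders as real data. It emulates:

* a roster whose first organization is the lead agency (always a
  respondent, since the lead administers the survey), with organization
  types drawn from a configurable mix;
* per-relation ground-truth networks in which each dyad (or arc) is a
  Bernoulli draw with probability `(1 - alpha) p + alpha star`, where
  `star` indicates dyads touching the lead (arcs into the lead when
  directed). `alpha = 0` gives expected density exactly `p`; `alpha = 1`
  a pure star, hence maximal centralization; intermediate values an
  interpolation whose expected density is correspondingly a mixture;
* reporting: each respondent reports its own row of the truth, each report
  independently flipped by false-negative/false-positive rates, with
  observed ties expressed as ordinal values drawn uniformly from the
  linked side of the cut-off (non-ties from the unlinked side) —
  discrepancies between dyad partners arise only through this noise, the
  simplest mechanism that exercises the mean-tie rule;
* organizational nonresponse as a configurable fraction (never the lead);
* CPAT item responses realized from provider totals drawn around a target
  team mean, adjusted item-by-item so rescoring recovers each drawn total
  to within half an item step (1/14);
* perception endorsements as independent Bernoulli draws per responding
  organization and item.

Default parameters are fixed at the study conditions the package is
designed around: 15 organizations with one nonrespondent (a 93.3%
response rate), per-relation true densities near the reported range
(0.648 contact down to 0.10 shared resources), modest hub weight 0.25,
reporting noise of 10% false negatives and 2% false positives, and a CPAT
block targeting mean 46.6 with provider sd 2.47 — the distribution of the
antecedent multi-team survey the cases were drawn from. Where a value had
no published anchor (the noise rates, `alpha`, provider count), it was set
once to what a survey methodologist would consider realistic for
organizational self-reports and is documented here rather than tuned.

What the generator deliberately does **not** model: correlated reporting
styles (an organization that over-reports every partner), dependence
between relations (contact and referral ties are drawn independently),
degree heterogeneity beyond the single hub, and item-level CPAT factor
structure. Passing recovery tests therefore demonstrates that the
pipeline's arithmetic is faithful under the stated observation model, not
that real survey data meet that model.

All randomness flows from one seed; each stage (roster, each relation's
truth, each relation's responses, CPAT, perceptions) derives its own
substream deterministically, so any object can be regenerated in
isolation and identical seeds reproduce byte-identical tables.

## Numerical and degenerate-input choices

* Density requires `n >= 2`, centralization `n >= 3`; smaller inputs are
  errors, not NaNs. An all-zero network has centralization 0.
* `classify_band()` rejects scores outside [0, 1] rather than clamping.
* Ties at the discrepancy threshold are linked (inclusive ≥ rule),
  favouring reported connectivity; the threshold is configurable for
  sensitivity analysis.
* The contact scale has no level strictly between biannual and monthly,
  so "more than twice per year" and "monthly or more often" encode the
  same cut; the package treats them as one rule.
* Plot layouts are Fruchterman–Reingold under a caller-supplied seed, so
  figures are reproducible; node sizes are linear in centrality with a
  floor so isolates stay visible, and isolates are never dropped.

## Problem sizes used in the test suite

The suite validates metrics against brute-force pair enumeration on 200
seeded random graphs of up to 7 nodes, imputation recovery on 100 seeded
cases of 5–15 organizations, and parameter recovery on 500 replicates at
n = 15 (the acceptance script uses 300 replicates per diagnostic). These
sizes were chosen to match the scale of the networks the method is used
on — two-digit rosters — where exhaustive checking is cheap and exact.

## Known limitations

* Valued (non-binary) network analysis, ERGM/QAP inference and
  longitudinal tie dynamics are out of scope; the pipeline ends at binary
  sociomatrices and descriptive measures.
* Directed-relation centralization on the total-degree basis is not
  defined here (no standard normalizer under the distinct-neighbour
  convention); use in- or out-degree.
* The missing mask records unobservable dyads but downstream measures
  treat them as 0-ties, which understates density when nonresponse is
  concentrated; the 30% guard bounds, but does not remove, this bias.
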