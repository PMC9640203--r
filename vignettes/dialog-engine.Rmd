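---
title: "The dialog-graph engine: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The dialog-graph engine: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chatflow)
```

## The model

A content pack is a typed directed graph. Vertices carry dialog content or
control logic; labeled edges are the legal transitions. A *turn* is the
unit of execution: starting from the user's current vertex, the engine
consumes one input, then traverses edges — emitting message bubbles and
attachments, applying variable updates, evaluating branch conditions —
until it reaches a vertex that requires input again or the session ends.
Nothing in traversal is random: given a graph, a seed and an input
sequence, a session replays byte for byte, which is what makes scripted
regression testing of clinical content possible.

The graph is partitioned into modules, each with one entry node and at
least one exit. Modules play three roles: `onboarding` (the fixed opening
sequence), `activity` (short, repeatable skill-teaching units offered
from a menu), and `outro` (the wrap-up with an optional assessment
recheck). This mirrors how such chatbots are actually authored: domain
experts write small self-contained units, and the engine handles
sequencing between them.

Assumptions worth stating explicitly:

* **Variables are simple.** Session variables are integers, booleans or
  short strings, and conditions use a closed operator set
  (`eq ne lt le gt ge is_set`). The content this engine targets only ever
  needs simple gating (e.g. serving a module when a flag is set); a
  full expression language would expand the validation surface for no
  authoring benefit.
* **Branches must say what happens when a variable is unset.** Any
  comparison against an unset variable routes to the branch's `default`
  edge; the validator warns when a branch lacks one, and the engine
  treats hitting that case without a default as a content fault.
* **Cycles are legal only through user input.** Menus repeat, so cycles
  through input-accepting nodes are normal. A cycle through only
  auto-advancing nodes could never end a turn, so the validator reports
  it as an error (not merely a warning), and the engine's `max_steps`
  cap (default 200 steps per turn) backstops anything the validator
  missed.

## Re-entry and assessment phases

The engine exposes one built-in variable, `session_index`, and otherwise
keys nothing on user history: the *content* decides what a returning user
sees by branching on it. The shipped demo pack gives first-time users the
full onboarding (intro, consent, worry item, psychoeducation) and
returning users just a greeting plus the worry item before the menu.
Whether an unfinished first onboarding should repeat in full is genuinely
undecidable from the behavior this engine models, so re-entry here depends
only on `session_index`.

The single worry item (integer 0–10, anchored "no worries" / "totally
freaking out") is recorded with a phase derived from context: `onboarding`
for the very first administration of a first session, `intro` for
session-opening administrations after that, and `outro` when the item sits
in an outro-role module. The outro administration is optional by design —
a decline records nothing rather than recording a sentinel.

## Free-text routing and safety

Typed text resolves with a strict precedence: **risk phrase → local
intent edge → priority intent → fallback**. The ordering encodes two
principles: safety preempts everything, and locally authored responses
beat generic digressions (an author who configured a `sadness` edge at a
node wants that response served there, even though `low_mood` is a
priority intent).

The default classifier is a deterministic keyword scorer: each intent's
best-matching pattern scores `tokens(pattern) / tokens(input)` (capped at
1), after both sides are lower-cased and stripped of punctuation, with
word-boundary matching so "suicideprevention" does not match "suicide".
Ties break lexicographically on intent id — arbitrary, but documented and
stable, which matters more here than cleverness. There is deliberately no
confidence threshold by default: the best match wins, and the interface
is pluggable for anyone wanting a statistical classifier. The registry
ships with 40 intents; the emotion and priority intents are fixed by the
architecture, the remainder are fixture content.

Two risk categories behave differently, which is an interpretation this
package commits to: **self-harm** phrases run the fixed escalation
protocol — confirmation question, empathy message, direction to a
helpline, session shutdown — while **abuse** phrases route as a priority
digression into the supportive violence module. Escalation on every
self-harm signal but digression for abuse keeps the person in the
conversation where content can direct them to the right services. Two
further choices the protocol itself forces: the confirmation step implies
a denial path, and the least-harm default on denial is to resume the
interrupted node verbatim; and the shipped hotline text is a placeholder
by design, because a research artifact must never carry a stale real
crisis number.

After a priority digression the user is *not* returned to the interrupted
node: the digressed-to module runs to its exit and control falls back to
the module menu. Digression is a signal that the user's agenda changed;
silently resuming the old thread would contradict it. The origin node is
kept on the session while the digression is in progress, so usage
analytics can count and locate digressions.

## Pacing

Conversational pacing is annotation, never behavior: the engine computes
`delay = min(cap, base + rate × nchar)` per message (defaults 300 ms base,
10 ms/character, 2000 ms cap — values in the range that reads as "typing"
without stalling the chat) and inserts typing indicators, but the engine
itself never sleeps. Only an interactive channel turns delays into real
time; in test mode every delay is zero, which keeps the whole suite and
all replays instant without changing message order or content.

## Privacy model of the event log

The analytics log records the series of activities and intents — session
starts and ends, module starts and completions, detected intents,
digressions, assessment phases and scores, escalations — and never raw
user text. This is enforced structurally: event payloads reject any key
from a designated free-text set at construction, so a privacy regression
cannot pass the type layer, and the test suite additionally greps
serialized logs for sentinel utterances fed to the engine. Timestamps come
from a deterministic logical clock (a fixed epoch plus an event counter),
which keeps replays reproducible; wall-clock time is never consulted.

## Cohort summaries

`summarize_cohort()` computes the standard uptake table of a chatbot open
trial. Percentages are rounded half-up at the precision they are
conventionally reported (1 decimal for demographic breakdowns and score
means, 0 decimals for the completion percentage), so printed counts
reproduce printed percentages exactly. The pre/post denominator — users
with at least one session-opening score who reached the outro offer — is
exposed as an explicit field rather than inferred, because the mapping
from "logged in" to "eligible for the pre/post measure" is exactly the
kind of quantity a reader should be able to audit. Pre/post pairs come
from the *same session only* (first opening score, first outro score of
the session containing the completed pair); cross-session pairing would
silently compare different episodes of worry. With no completers the
summary reports absent values, not zeros, and with one completer the SDs
(sample, n−1) are absent.

## The trial simulator

`simulate_trial()` generates a synthetic cohort by running the real
engine: each simulated login replays the demo pack with sampled menu
choices, sampled worry scores and sampled dropout, so the event log has
exactly the schema and ordering live usage would produce — the analytics
are never fed hand-built data in the pipeline tests.

The default configuration emulates a two-week open-trial uptake pattern:
393 registrations, login probability 238/393, target-age probability
127/238, 70.9% female and 47.2% NZ European among target-age users,
pre-score distribution centred at 5.1 (SD 2.6), a mean within-session
reduction of 0.8 (to 4.3), outro-reach probability 81/127, recheck
completion 30/81, and return probability 31/127. Where the emulated
pattern pins only one or two categories of a breakdown, the remaining
probability mass is spread over invented categories including an explicit
`other_unspecified` bucket. Two parameters have no empirical anchor and
were fixed once as modelling choices: the post-score noise SD (1.5, so
the post distribution stays realistically dispersed after conditioning on
the pre score) and the out-of-range age band (25–64).

Worry scores are the simplest model compatible with a mean, an SD and a
0–10 integer range: a normal truncated to [0,10] (by resampling) and
rounded to integers, with `post = clamp(round(pre − 0.8 + noise), 0, 10)`.
Truncation pulls the realized pre mean slightly toward the scale midpoint
(about 5.07 for these parameters) and boundary clamping nudges the post
mean up by a similar hair; both effects are well inside sampling noise at
the cohort sizes used and are the reason recovery checks use a standard-
error band rather than exact equality.

What the simulator deliberately does **not** model: engagement duration
(the 11-minute mean session length of real deployments), time-of-day
usage, message-level timing, correlation between demographics and
behavior, and any treatment-effect mechanism — the pre→post shift is a
configured emulation target, not a causal claim. Passing tests therefore
show that the pipeline *arithmetic* is right and the generator recovers
its own parameters; they say nothing about real-world effectiveness.

## Problem sizes and numerical checks

The acceptance computation simulates 7,000 registrations (≈600 completers)
so the recovered means are estimated with standard errors near 0.1; the
in-suite recovery test uses 2,000 registrations, and the property suites
run over ten-node random graphs (a dozen seeds each for round-tripping,
reachability-oracle agreement and engine-vs-naive-interpreter
equivalence). Recovery assertions allow `3·SE + 0.05`, the extra term
being the discretization of means reported to one decimal. Rounding is
half-up with a relative epsilon so that quotients like 100·30/81, which
sit exactly on a .5 boundary in decimal but not in binary, round the way
a person computing from the printed counts would round them.

## Known limitations

* The keyword classifier has no notion of negation ("I'm not sad"
  classifies as sadness); the pluggable interface exists precisely so a
  deployment can swap in something better without touching routing.
* Validation treats reachability graph-theoretically; a branch whose
  condition is statically unsatisfiable can still hide content.
* The session archive persists progress and saved items but not
  mid-module position; resuming mid-node is out of scope.
* One process, one user: there is no concurrency model, no scheduling,
  and no messaging-platform adapter — the outbound-message contract is
  the integration point for any real channel.
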