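---
title: "Seed-and-extend DNA search in blatr: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seed-and-extend DNA search in blatr: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blatr)
```

## The problem

BLAT-style search answers the question "where in a genome does this DNA
sequence come from?" fast enough for interactive use: the target genome is
indexed once into fixed-length k-mer *tiles*, and each query is aligned by
finding exact tile matches (*seeds*), grouping collinear seeds, and
extending them into gapless high-scoring segments that are then chained.
`blatr` implements this pipeline natively in R, together with the
surrounding machinery a practitioner needs: the `.2bit` genome archive
format, the 21-column PSL alignment format, a long-lived TCP search server
so one index build amortises many queries, and a deterministic synthetic
benchmark generator so everything can be validated without external data.

This vignette explains the model, the parameters that matter, the design
decisions that were genuinely open, and what the shipped tests do and do
not demonstrate.

## The index

The target is packed 2 bits per base (T=0, C=1, A=2, G=3 — the same code
table as the `.2bit` format, so a packed byte and a tile code agree).
Tiles of `tile_size` bases (default **11**, the classic DNA tile) are
sampled from the target at offsets `0, step, 2*step, ...` with
`step_size = tile_size` by default. Tiles spanning an `N` are skipped.
Tile codes occurring at more than `overused_threshold` positions
(default **1024**) are dropped from the lookup and recorded — the standard
defence against low-complexity and repeat tiles flooding the seed stage.

The query side is scanned at step 1 on both strands (the minus strand
scans the reverse complement). Stepping only the target preserves the
recovery guarantee below while keeping the index sparse; stepping both
sides would lose it.

**Recovery guarantee.** Any exact planted substring of length at least
`3*tile_size` with no `N`s is recovered in full. Proof sketch: a planted
interval of length `3k` on the target contains at least two complete
step-aligned tiles (pigeonhole over offsets modulo `k`), both of which
seed the same diagonal; the resulting cluster passes `min_seeds = 2`, and
ungapped extension over an exact region accumulates score monotonically,
so the x-drop never triggers and the whole query is covered. The test
suite verifies this over 500 random plantings, and separately at the
benchmark scale (2,850 queries of 1000–3000 bp against a 2 Mb genome).

## Seeding, clustering, extension

Each seed is a `(query_offset, target_offset)` pair; collinear seeds share
a *diagonal* (`target_offset - query_offset`). Seeds are grouped by
`(strand, target)` and then single-linkage clustered on the diagonal:
consecutive diagonals further than `max_gap` (default **100** bases) apart
start a new cluster; clusters with fewer than `min_seeds` (default **2**)
hits are discarded.

Within a cluster, each distinct diagonal contributes one gapless block:
the seed-covered core is extended base by base in both directions with
score `+match_score` per match and `mismatch_cost` per mismatch
(defaults **+1/−1**; an `N` on either side never matches and scores like a
mismatch). Extension stops when the running score falls
`match_score * tile_size` below its maximum (the *x-drop*), and the block
is trimmed back to the maximum. **Tie-break:** at equal score the shorter
extension wins. This makes "core plus two independent one-sided
extensions" coincide exactly with the unique shortest maximal-scoring
segment, which is what the brute-force oracle in the test suite computes;
preferring the longer extension instead would disagree with any exhaustive
oracle on zero-net-gain boundary oscillations (a mismatch immediately
"paid back" by a chance match), which arise at an appreciable rate in
random flanks.

Blocks from different diagonals are chained by a small dynamic program
that maximises total block score over chains strictly increasing and
non-overlapping in both query and target, with a unit penalty per gap
opened (the fixtures are substitution-only, so chains are almost always a
single block; the DP exists so that indel-containing inputs still produce
valid, sensibly ordered records). Gaps between chained blocks are counted
into the PSL `qNumInsert`/`qBaseInsert`/`tNumInsert`/`tBaseInsert`
fields.

A record is emitted only if its score
(`matches − misMatches − nCount`) reaches `min_score` (default **30**) and
its percent identity `100 * matches / (matches + misMatches)` reaches
`min_identity` (default **90**). `repMatches` is always 0: soft-masked
(lowercase) bases align like their uppercase forms and are indexed
normally; no repeat-aware scoring is attempted.

Output order is deterministic: query input order, then descending score,
then `(tName, tStart)`. Two runs on identical inputs produce byte-identical
PSL.

## The 2bit codec

Archives follow the published UCSC layout byte for byte: the
`0x1A412743` signature, version 0, an index of names and offsets, and per
sequence the packed DNA plus explicit *N-blocks* and *mask-blocks*
(0-based starts and sizes). Bases inside N-blocks are stored as code 0 and
always restored as `N`; lowercase is restored from the mask blocks, so
`decode(encode(x))` is exact including case. Archives are written
little-endian and read in either byte order (the signature reveals the
order). Random access (`fetch_subsequence()`) decodes only the bytes
covering the requested window. Interoperability is tested in both
directions against an independent third-party `.2bit` reader/writer where
one is installed. The >4 Gb long-sequence extension is out of scope.

All coordinates everywhere in the package are 0-based half-open, matching
both `.2bit` and PSL conventions.

## The server

`start_server()` binds a TCP listener — retrying `port+1 ... port+max_retries`
when the requested port is busy (`can_retry`, default on) — and then forks
a worker that builds the index and serves. Binding *before* forking means
the caller knows the bound port immediately and the archive passes by
memory; no files are involved at any point, which the tests assert by
watching the session temporary directory during querying.

The wire protocol is deliberately simple line-oriented text (`status`,
`query <name> <length>` + one line of residues, `quit [token]`;
responses are a status line, PSL lines, and a `.` terminator). No
published byte-level protocol exists for this kind of daemon's binary
dialect, so the package defines its own and documents it; compatibility
with the UCSC binary protocol would be a separate adapter and is a
non-goal. Readiness is a server-side state reached only after the index is
complete and reported in `status` — never inferred from log files.
`wait_server()` polls at 0.2 s (fixed in this version). `stop_server()`
from a non-owner is honoured only when the server was started with
`allow_remote_stop` (the CLI turns this on by default so `blatr server
stop` works across processes; the library default is off). Stopping an
already-stopped server is an idempotent success. `attach_server()` probes
an address and returns an unowned handle when the server's tile and step
sizes match the expected parameters, raises a mismatch error naming the
fields when they do not, and returns `NULL` when nothing is listening.

The server is single-threaded by design: requests are serialised, which
makes the parity guarantee trivial to state — for any inputs, the PSL
bytes produced over the socket are identical to `align()` in-process —
and keeps the implementation auditable. Concurrent clients interleave at
the granularity of single queries.

## Synthetic benchmark fixtures

`make_genome()` draws a uniform-composition ACGT sequence; queries are
planted with `plant_queries()` as uniformly sampled substrings of
1000–3000 bp, reverse-complemented with probability 0.5 and point-mutated
at a configurable per-base rate, with an exact truth table returned. The
benchmark-shaped suite is eight sets of
`{50, 50, 100, 200, 300, 400, 500, 600}` queries against a shared 2 Mb
genome — the seven canonical set sizes with the smallest duplicated to
make eight; the duplication choice is a package convention. At mutation
rate 0 the suite must achieve `recovery_rate() == 1.0`; at 1% substitution
the expectation is ≥ 0.95 (point mutations only rarely destroy every
step-aligned tile at these lengths — this tolerance is a design choice,
not an external constant).

What the generator deliberately does **not** emulate: GC skew, repeat
families, segmental duplication, indels, or sequencing-error profiles.
Uniform backgrounds make the recovery guarantee provable and make random
off-target alignments rare enough that the oracle-equivalence tests are
sharp; they also mean that passing tests bound behaviour on *repetitive*
real genomes only weakly. The overused-tile filter is exercised by
dedicated low-complexity constructions instead.

Problem sizes in the shipped tests (a 2 Mb genome, 2,850 benchmark
queries, 1,000-record codec round trips, 200 oracle instances, 500
plantings) were chosen as the smallest sizes at which each property is
meaningfully stressed.

## Numerical and degenerate-input choices

* Tile codes are accumulated in doubles; at the maximum `tile_size` of 18
  a code is `4^18 < 2^53`, so arithmetic is exact.
* `.2bit` field values are read and written through explicit unsigned
  32-bit byte arithmetic (R has no native unsigned type).
* Empty inputs are identities, not errors: an empty FASTA parses to an
  empty record list, an empty archive encodes/decodes, `align()` of zero
  queries is an empty PSL, `query_server()` of zero queries never touches
  the socket.
* Queries shorter than `tile_size` cannot seed and return empty results
  (documented, not an error).
* A zero-length interval in `fetch_subsequence()` is `""`.
* `percent_identity()` is undefined (`NA`) when no non-N bases align.
* Residues outside `ACGTN` (either case) are rejected at parse time with
  the record name and offset rather than coerced: the 2bit format cannot
  represent other ambiguity codes distinctly, and silent loss is worse
  than an explicit failure.

## Known limitations

* DNA only: no translated (protein) search modes, no spliced/intron-aware
  chaining, and no repeat libraries.
* Ungapped extension with simple chaining: no affine-gap dynamic program,
  so alignments across indels are reported as multi-block chains rather
  than optimal gapped alignments.
* One index per server; no dynamic index updates, distribution, or
  multi-tenancy; no TLS or authentication on the wire protocol.
* The `.2bit` long-sequence (>4 Gb) extension is unsupported.
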