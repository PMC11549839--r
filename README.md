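# blatr

BLAT-style DNA sequence search, self-contained and fully in memory.

`blatr` is for people who need fast "where does this sequence come from?"
lookups against a genome inside R — the workflow classically served by a
`gfServer`/`gfClient` pair — without shelling out to external binaries or
juggling intermediate files. It provides:

* a byte-exact codec for the UCSC **`.2bit`** genome archive format
  (N-blocks and soft-mask blocks included), with FASTA conversion in both
  directions and random access;
* the **seed-and-extend aligner**: a k-mer tile index over the target,
  seed finding on both strands, diagonal clustering, ungapped x-drop
  extension and block chaining, emitting standard 21-column **PSL**
  records and a **QueryResult → Hit → HSP** object model;
* a TCP **search server** with ergonomic lifecycle management — start,
  stop, status, wait-until-ready, automatic port retry, attaching to an
  already-running server — whose socket results are byte-identical to
  in-process alignment;
* a deterministic **synthetic benchmark generator** (planted queries with
  a truth table) so every property is testable without downloads;
* a **command-line interface** with bash/zsh/fish completion.

## The method in brief

The target genome is indexed once: non-overlapping tiles of *k* = 11
bases (codes T=0, C=1, A=2, G=3, two bits per base) are sampled every
*k* bases; tiles spanning `N` are skipped and tiles occurring at more
than 1024 positions are dropped as overused. A query of length *m* is
scanned at every offset on both strands; each exact tile match is a seed
at diagonal *t − q*. Seeds sharing a strand and target are clustered
into diagonal bands of width 100; clusters with ≥ 2 seeds are extended
gaplessly (+1 match / −1 mismatch, x-drop of *k*, trimmed back to the
score maximum, shorter extension preferred at ties) and chained into a
PSL record, kept when score ≥ 30 and identity ≥ 90%. Any exact planted
substring of length ≥ 3*k* is provably recovered in full (pigeonhole
over step-aligned tiles). All parameters are `align_params()` arguments.

## Worked example

```r
library(blatr)

genome  <- make_genome(2e5, seed = 7, name = "chrS")   # synthetic 200 kb target
archive <- encode_twobit(list(genome))                 # in-memory .2bit
index   <- build_tile_index(list(genome))
index
#> <tile_index> 1 target(s), 200,000 bp; tile 11 step 11; 18,181 tile position(s), 0 overused code(s) dropped

planted <- plant_queries(genome, n = 3, length_range = c(1000, 3000),
                         mutation_rate = 0.01, seed = 8)
records <- align(planted$queries, index, archive)
cat(write_psl(records))
#> 2863  24  0  0  0  0  0  0  -  q0001  2887  0  2887  chrS  200000  86606   89493   1  2887,  0,  86606,
#> 2308  23  0  0  0  0  0  0  -  q0002  2331  0  2331  chrS  200000  115942  118273  1  2331,  0,  115942,
#> 2185  21  0  0  0  0  0  0  +  q0003  2206  0  2206  chrS  200000  95488   97694   1  2206,  0,  95488,

psl_to_query_results(records)[[1]]
#> <query_result> q0001: 1 hit(s), 1 HSP(s)
#>   chrS: 1 HSP(s), best score 2839 (99.2% id, -, t:86606-89493)

recovery_rate(planted$truth, records)
#> [1] 1
```

Reading the first PSL line: query `q0001` (2887 bp, planted with 1%
substitutions) aligns on the minus strand to `chrS:86606-89493` as a
single block with 2863 matching bases and 24 mismatches — exactly the 24
planted mutations (`planted$truth$mutations[1]`), at exactly the planted
position.

The same search over a socket, with lifecycle management:

```r
h <- start_server(server_config(port = 17779), archive)
wait_server(h, timeout = 60)        # "ready" once the index is built
res <- query_server(h, planted$queries)   # identical bytes to align()
status_server(h)$request_count      # 3
stop_server(h)
```

## Command line

```sh
blatr="Rscript $(Rscript -e 'cat(system.file("cli","blatr",package="blatr"))')"
$blatr fa2twobit ref.fa ref.2bit
$blatr server start --2bit ref.2bit --port 17779     # prints the bound port
$blatr server wait --port 17779
$blatr client queries.fa --port 17779 > hits.psl
$blatr server stop --port 17779
$blatr completion bash > /etc/bash_completion.d/blatr
```

`--inprocess --2bit ref.2bit` runs the client without a server and
produces byte-identical PSL. Exit codes: 0 success, 1 runtime failure,
2 usage error; data on stdout, logs on stderr.

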