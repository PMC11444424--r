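# CURD displacement-record file format (version 1)

Little-endian binary. One file holds the displacement triplets of one
analysis run, together with its lag table.

| offset            | size | type        | content                          |
|-------------------|------|-------------|----------------------------------|
| 0                 | 4    | bytes       | magic `"CURD"`                   |
| 4                 | 4    | uint32      | format version, = 1              |
| 8                 | 4    | uint32      | n_lags                           |
| 12                | 8×n_lags | float64 | lag times in ns, ascending       |
| 12 + 8·n_lags     | 8    | uint64      | n_records                        |
| ...               | 12×n_records | 3 × uint32 | records                   |

Each record is `(v_lo, v_hi, lag_index)`: 0-based mesh vertex indices with
`v_lo <= v_hi` (the lower vertex first; geodesic distance is symmetric), and
a 0-based index into the lag table. Files written by `sort_records()` +
`write_records()` are sorted by the full `(v_lo, v_hi, lag_index)` key, so
all records sharing a lower vertex form one contiguous block and the bytes
are reproducible across runs.

Readers must reject files with a wrong magic or version and report the byte
offset of any truncation.
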