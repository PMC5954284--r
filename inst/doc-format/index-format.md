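# Token-existence index file format (`.ssix`), version 1

All integers little-endian. `int32` = 4-byte signed integer, `f64` = 8-byte
IEEE double (all stored quantities are exact integers well below 2^53).
Strings are length-prefixed: `int32` byte count, then raw bytes (no
terminator).

## Header

| field          | type   | meaning                                   |
|----------------|--------|-------------------------------------------|
| magic          | 4 bytes| `53 53 49 58` (`"SSIX"`)                  |
| version        | int32  | format version, currently 1               |
| token_size     | int32  | token length `n`                          |
| num_bins       | f64    | total bin count `t`                       |
| stride         | f64    | bin stride in bases                       |
| overlap        | f64    | bin overlap in bases                      |
| genome_length  | f64    | total reference length in bases           |
| genome_name    | string | label                                     |
| n_records      | int32  | number of reference records               |

Then `n_records` record entries, each:

| field     | type   | meaning                          |
|-----------|--------|----------------------------------|
| name      | string | record (chromosome/contig) name  |
| length    | f64    | record length in bases           |
| num_bins  | f64    | bins allotted to this record     |

Record offsets and bin offsets are not stored; they are the cumulative sums
of the lengths / bin counts in file order.

## Bit payload

`4^token_size` rows in token-code order (code 0 = `AA...A`). Each row holds
the existence bits of one token across bins `0..t-1` in bin order, packed 8
bits per byte, least-significant bit first (bin `8k` is bit 0 of byte `k`),
padded with zero bits to `ceil(t/8)` bytes. Total payload:
`4^token_size * ceil(t/8)` bytes. Nothing follows the payload.

A reader must reject files with wrong magic, unknown version, header/payload
truncation, or a payload whose size disagrees with the header.
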