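# Bundled data

## contact_potential_synthetic.tsv

A 20 x 20 symmetric table of pairwise residue contact energies (RT units,
dimensionless) used as default link weights. **This table is synthetic**: it
is a reconstruction, not a transcription of a published pairwise table. It
is built as

    e(a, b) = alpha + beta * ( -h_a * h_b / max(h)^2 + 0.30 * z_a * z_b )

where `h` is the published one-body contact-energy-derived hydrophobicity
scale (Miyazawa & Jernigan, Macromolecules 18:534, 1985; the product form
captures the dominant one-body structure of statistical contact potentials)
and `z` is the formal side-chain charge (+1 Arg/Lys, -1 Asp/Glu, +0.5 His),
so that like-charged pairs are repulsive. The affine constants are fixed so
the global minimum and maximum equal -1.19 and 0.76, the printed range of
the self-consistent inter-residue contact potential this table stands in
for; entries are rounded to two decimals (entries that would round to 0.00
are nudged to +/-0.01 so every pair is strictly attractive or repulsive).

Sign convention: negative = attractive ("similar" weight), positive =
repulsive ("dissimilar" weight).

Format: tab-separated, header row and first column of three-letter residue
codes, full matrix. `loadPotentialTable()` reads this format (also
lower-triangular and comma-separated variants), validates symmetry,
completeness and the [-1.19, 0.76] range, and accepts any drop-in
replacement table with the same layout (use `rangeCheck = FALSE` for
potentials with a different range).
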