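# Errata for the packaged ledger transcriptions

The two ledgers under `extdata/` (`candidate_sites_table.tsv`,
`validated_sites_table.tsv`) are transcribed verbatim from their published
source, including the following internal inconsistencies.  The code never
"fixes" these silently; they are recorded here so downstream users know the
fixtures are faithful, not curated.

1. Position/gene pairing. The validated table pairs position 14,198,871 with
   AT2G16586 and position 7,191,297 with AT3G41768 — the *reverse* of the
   pairing in the candidate table (rows 13 and 55), which assigns 14,198,871
   to AT3G41768 and 7,191,297 to AT2G16586. Both pairings are retained as
   printed in their respective tables.

2. Efficiency for AT3G41768. The running text gives the editing efficiency
   as 45.65%, while the validated table prints 45.54 (12-day column). The
   table value is the one transcribed.

3. Gene list discrepancy. The text names AT5G02670 among the seven validated
   genes in one place and AT1G05670 in another; the validated table carries
   AT5G02670, which is what the fixture keeps.

4. U-to-C gene counts. The reported counts of genes carrying U-to-C
   conversions disagree across figures (50 vs. 54) and with the number of
   distinct gene identifiers in the candidate table (53, counting
   AT2G16586 and AT5G52530 once each). No reconciliation is attempted.
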