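Local mirror of public PDB entries used by the reference-comparison tests.

The tests in test-acceptance.R that recompute published values from deposited
structures look here for coordinate files named <ID>.pdb (for example
4XXJ.pdb, 1IW6.pdb, 7Z09.pdb, 6S6C.pdb, 1QHJ.pdb, 1C3W.pdb, 1BRR.pdb).
Populate this directory with the files from https://files.rcsb.org/download/
to run those comparisons; without the files they fail with a file-not-found
error. No coordinate data is redistributed with the package.
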