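#!/usr/bin/env python
"""Batch molecular featurizer backed by RDKit.

Reads SMILES, one per line, and writes a JSON array with one record per
input line. A record is either {"error": <reason>} or contains, depending
on --mode (comma-separated subset of graph,morgan,smarts):

  canonical : RDKit canonical SMILES (always present on success)
  atoms     : [symbol, heavy_degree, total_H, formal_charge, aromatic] rows,
              in the atom order of the re-parsed canonical SMILES
  bonds     : [begin_idx, end_idx, order, conjugated, in_ring] rows (0-based)
  bits      : 0-based on-bit indices of the hashed Morgan fingerprint
  motifs    : 0/1 substructure-presence flags, one per --smarts pattern

Called by the R package nfscreen; not a user-facing tool.
"""
import argparse
import json
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import rdFingerprintGenerator

RDLogger.DisableLog("rdApp.*")

BOND_ORDER = {
    Chem.BondType.SINGLE: "single",
    Chem.BondType.DOUBLE: "double",
    Chem.BondType.TRIPLE: "triple",
    Chem.BondType.AROMATIC: "aromatic",
}


def featurize(smi, modes, morgan_gen, smarts_pats):
    mol = Chem.MolFromSmiles(smi)
    if mol is None:
        return {"error": "unparsable SMILES"}
    if mol.GetNumHeavyAtoms() == 0:
        return {"error": "no heavy atoms"}
    can = Chem.MolToSmiles(mol)
    # Re-parse so every spelling of a molecule yields one deterministic
    # atom order (the canonical-SMILES order).
    mol = Chem.MolFromSmiles(can)
    rec = {"canonical": can}
    if "graph" in modes:
        rec["atoms"] = [
            [a.GetSymbol(), a.GetDegree(), a.GetTotalNumHs(),
             a.GetFormalCharge(), int(a.GetIsAromatic())]
            for a in mol.GetAtoms()
        ]
        bonds = []
        for b in mol.GetBonds():
            order = BOND_ORDER.get(b.GetBondType())
            if order is None:
                return {"error": "unsupported bond type %s" % b.GetBondType()}
            bonds.append([b.GetBeginAtomIdx(), b.GetEndAtomIdx(), order,
                          int(b.GetIsConjugated()), int(b.IsInRing())])
        rec["bonds"] = bonds
    if "morgan" in modes:
        rec["bits"] = sorted(morgan_gen.GetFingerprint(mol).GetOnBits())
    if "smarts" in modes:
        rec["motifs"] = [int(mol.HasSubstructMatch(p)) for p in smarts_pats]
    return rec


def main():
    ap = argparse.ArgumentParser()
    ap.add_argument("--infile", required=True)
    ap.add_argument("--outfile", required=True)
    ap.add_argument("--mode", default="graph")
    ap.add_argument("--radius", type=int, default=2)
    ap.add_argument("--nbits", type=int, default=1024)
    ap.add_argument("--smarts", action="append", default=[])
    args = ap.parse_args()

    modes = set(args.mode.split(","))
    morgan_gen = None
    if "morgan" in modes:
        morgan_gen = rdFingerprintGenerator.GetMorganGenerator(
            radius=args.radius, fpSize=args.nbits)
    smarts_pats = []
    if "smarts" in modes:
        for s in args.smarts:
            p = Chem.MolFromSmarts(s)
            if p is None:
                sys.stderr.write("bad SMARTS pattern: %s\n" % s)
                sys.exit(2)
            smarts_pats.append(p)

    with open(args.infile) as fh:
        smiles = [line.strip() for line in fh if line.strip()]
    out = [featurize(s, modes, morgan_gen, smarts_pats) for s in smiles]
    with open(args.outfile, "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main()
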