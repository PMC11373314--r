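"""Batch chemistry-property oracle.

Reads SMILES (one per line) and writes a CSV with, per molecule: RDKit
parseability, canonical SMILES, QED, Ertl-Schuffenhauer synthetic
accessibility score, PAINS filter pass, ring-aromaticity pass (no double
bond inside a non-aromatic ring), and optionally whether two query
fragments are contained as substructures.
"""
import argparse
import csv
import sys


def main():
    ap = argparse.ArgumentParser()
    ap.add_argument("--infile", required=True)
    ap.add_argument("--outfile", required=True)
    ap.add_argument("--frag1", default=None)
    ap.add_argument("--frag2", default=None)
    ap.add_argument("--graphfile", default=None,
                    help="also dump kekulized atom/bond tables")
    args = ap.parse_args()

    from rdkit import Chem, RDLogger
    from rdkit.Chem import QED, RDConfig
    from rdkit.Chem.FilterCatalog import FilterCatalog, FilterCatalogParams
    import os
    sys.path.append(os.path.join(RDConfig.RDContribDir, "SA_Score"))
    import sascorer

    RDLogger.DisableLog("rdApp.*")

    params = FilterCatalogParams()
    params.AddCatalog(FilterCatalogParams.FilterCatalogs.PAINS)
    pains = FilterCatalog(params)

    def strip_dummies(smiles):
        m = Chem.MolFromSmiles(smiles)
        if m is None:
            return None
        em = Chem.RWMol(m)
        for idx in sorted([a.GetIdx() for a in em.GetAtoms()
                           if a.GetAtomicNum() == 0], reverse=True):
            em.RemoveAtom(idx)
        q = em.GetMol()
        try:
            Chem.SanitizeMol(q)
        except Exception:
            return None
        return q

    q1 = strip_dummies(args.frag1) if args.frag1 else None
    q2 = strip_dummies(args.frag2) if args.frag2 else None

    def arom_ring_pass(mol):
        ri = mol.GetRingInfo()
        for bond_ring in ri.BondRings():
            bonds = [mol.GetBondWithIdx(b) for b in bond_ring]
            ring_aromatic = all(b.GetIsAromatic() for b in bonds)
            if ring_aromatic:
                continue
            for b in bonds:
                if b.GetBondType() == Chem.BondType.DOUBLE:
                    return 0
        return 1

    with open(args.infile) as fh:
        smiles = [ln.rstrip("\n") for ln in fh if ln.strip()]

    graph_rows = []

    def dump_graph(i, mol):
        m = Chem.Mol(mol)
        try:
            Chem.Kekulize(m, clearAromaticFlags=True)
        except Exception:
            graph_rows.append([i, 0, "", ""])
            return
        syms = " ".join(a.GetSymbol() if a.GetAtomicNum() > 0 else "*"
                        for a in m.GetAtoms())
        charges = any(a.GetFormalCharge() != 0 for a in m.GetAtoms())
        order_of = {Chem.BondType.SINGLE: 1, Chem.BondType.DOUBLE: 2,
                    Chem.BondType.TRIPLE: 3}
        bonds = []
        for b in m.GetBonds():
            o = order_of.get(b.GetBondType())
            if o is None:
                graph_rows.append([i, 0, "", ""])
                return
            bonds.append(f"{b.GetBeginAtomIdx() + 1}-{b.GetEndAtomIdx() + 1}-{o}")
        graph_rows.append([i, 0 if charges else 1, syms, ";".join(bonds)])

    with open(args.outfile, "w", newline="") as out:
        w = csv.writer(out)
        w.writerow(["index", "parsed", "canonical", "qed", "sa",
                    "arom_ring_pass", "pains_pass", "has_frag1",
                    "has_frag2"])
        for i, smi in enumerate(smiles, start=1):
            mol = Chem.MolFromSmiles(smi)
            if mol is None:
                w.writerow([i, 0, "", "", "", "", "", "", ""])
                continue
            row = [i, 1, Chem.MolToSmiles(mol),
                   f"{QED.qed(mol):.10f}",
                   f"{sascorer.calculateScore(mol):.10f}",
                   arom_ring_pass(mol),
                   0 if pains.HasMatch(mol) else 1]
            row.append("" if q1 is None else int(mol.HasSubstructMatch(q1)))
            row.append("" if q2 is None else int(mol.HasSubstructMatch(q2)))
            w.writerow(row)
            if args.graphfile:
                dump_graph(i, mol)

    if args.graphfile:
        with open(args.graphfile, "w", newline="") as gf:
            gw = csv.writer(gf)
            gw.writerow(["index", "ok", "atoms", "bonds"])
            for r in graph_rows:
                gw.writerow(r)


if __name__ == "__main__":
    main()
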