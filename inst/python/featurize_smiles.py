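"""RDKit helper invoked by the R package as a subprocess.

Modes (first argv):
  featurize <in_csv> <out_dir>   in_csv: drug_id,smiles -> atoms/bonds/mols csv
  match     <in_csv> <smarts>    prints drug_id,match(0/1) per row
  renumber  <in_csv> <seed>      prints drug_id,smiles with atoms renumbered

Only stdlib + RDKit; heavy-atom graphs (implicit hydrogens kept as counts).
"""
import csv
import os
import random
import sys

from rdkit import Chem
from rdkit import RDLogger

RDLogger.DisableLog("rdApp.*")


def read_input(path):
    with open(path, newline="") as fh:
        rd = csv.DictReader(fh)
        return [(row["drug_id"], row["smiles"]) for row in rd]


def featurize(in_csv, out_dir):
    rows = read_input(in_csv)
    os.makedirs(out_dir, exist_ok=True)
    with open(os.path.join(out_dir, "mols.csv"), "w", newline="") as fm, \
         open(os.path.join(out_dir, "atoms.csv"), "w", newline="") as fa, \
         open(os.path.join(out_dir, "bonds.csv"), "w", newline="") as fb:
        wm = csv.writer(fm)
        wa = csv.writer(fa)
        wb = csv.writer(fb)
        wm.writerow(["drug_id", "status", "n_atoms", "canonical_smiles"])
        wa.writerow(["drug_id", "atom", "atomic_num", "chirality", "degree",
                     "formal_charge", "num_h", "radicals", "hybridization",
                     "aromatic", "in_ring"])
        wb.writerow(["drug_id", "a1", "a2", "bond_type", "stereo",
                     "conjugated"])
        for drug_id, smi in rows:
            mol = Chem.MolFromSmiles(smi)
            if mol is None:
                wm.writerow([drug_id, "unparsable", 0, ""])
                continue
            if mol.GetNumAtoms() == 0:
                wm.writerow([drug_id, "empty", 0, ""])
                continue
            wm.writerow([drug_id, "ok", mol.GetNumAtoms(),
                         Chem.MolToSmiles(mol)])
            for a in mol.GetAtoms():
                wa.writerow([drug_id, a.GetIdx() + 1, a.GetAtomicNum(),
                             int(a.GetChiralTag()), a.GetDegree(),
                             a.GetFormalCharge(), a.GetTotalNumHs(),
                             a.GetNumRadicalElectrons(),
                             str(a.GetHybridization()),
                             int(a.GetIsAromatic()), int(a.IsInRing())])
            for b in mol.GetBonds():
                wb.writerow([drug_id, b.GetBeginAtomIdx() + 1,
                             b.GetEndAtomIdx() + 1, str(b.GetBondType()),
                             str(b.GetStereo()), int(b.GetIsConjugated())])


def match(in_csv, smarts):
    patt = Chem.MolFromSmarts(smarts)
    w = csv.writer(sys.stdout)
    w.writerow(["drug_id", "match"])
    for drug_id, smi in read_input(in_csv):
        mol = Chem.MolFromSmiles(smi)
        hit = 0 if mol is None else int(mol.HasSubstructMatch(patt))
        w.writerow([drug_id, hit])


def renumber(in_csv, seed):
    rng = random.Random(int(seed))
    w = csv.writer(sys.stdout)
    w.writerow(["drug_id", "smiles"])
    for drug_id, smi in read_input(in_csv):
        mol = Chem.MolFromSmiles(smi)
        if mol is None:
            w.writerow([drug_id, ""])
            continue
        order = list(range(mol.GetNumAtoms()))
        rng.shuffle(order)
        mol2 = Chem.RenumberAtoms(mol, order)
        w.writerow([drug_id, Chem.MolToSmiles(mol2, canonical=False)])


def main():
    mode = sys.argv[1]
    if mode == "featurize":
        featurize(sys.argv[2], sys.argv[3])
    elif mode == "match":
        match(sys.argv[2], sys.argv[3])
    elif mode == "renumber":
        renumber(sys.argv[2], sys.argv[3])
    else:
        raise SystemExit(f"unknown mode: {mode}")


if __name__ == "__main__":
    main()
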