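"""Batch molecule operations over RDKit for the npgen R package.

Protocol: one task per invocation.  stdin carries tab-separated records
(id <TAB> smiles [<TAB> extra]); stdout returns a tab-separated table with a
header row.  Rows never contain tabs (SMILES/InChI exclude them).  Invalid
molecules yield empty fields, never a crash, so row alignment with the R
caller is preserved.
"""

import argparse
import random
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem, Descriptors
from rdkit.Chem.MolStandardize import rdMolStandardize

RDLogger.DisableLog("rdApp.*")

PANEL10 = [
    "NumAromaticRings", "NumAliphaticRings", "MolLogP", "MolWt",
    "NumHAcceptors", "NumHDonors", "NumHeteroatoms", "TPSA",
    "NumRotatableBonds", "NumValenceElectrons",
]
PANEL27 = [
    "BalabanJ", "BertzCT", "NumAromaticRings", "HallKierAlpha", "Kappa1",
    "Chi0", "Chi0n", "Chi0v", "MolLogP", "MolMR", "MolWt", "ExactMolWt",
    "HeavyAtomCount", "HeavyAtomMolWt", "NHOHCount", "NOCount",
    "NumHAcceptors", "NumHDonors", "NumHeteroatoms", "RingCount",
    "FractionCSP3", "TPSA", "LabuteASA", "NumRotatableBonds",
    "NumValenceElectrons", "NumSaturatedRings", "NumAliphaticRings",
]

# druglike / NP-relevant elements; anything else trips the severe checker rule
ELEMENT_WHITELIST = {
    "H", "B", "C", "N", "O", "F", "Si", "P", "S", "Cl", "Se", "Br", "I",
    "Li", "Na", "K", "Mg", "Ca", "Zn", "Fe",
}

# default valences used by the explicit valence-violation rule (neutral atoms)
VALENCE_TABLE = {"C": 4, "N": 3, "O": 2, "F": 1, "Cl": 1, "Br": 1, "I": 1, "B": 3}


def read_rows():
    for line in sys.stdin:
        line = line.rstrip("\n")
        if not line:
            continue
        yield line.split("\t")


def emit(fields):
    sys.stdout.write("\t".join(str(f) for f in fields) + "\n")


def mol_from(smiles):
    if not smiles:
        return None
    return Chem.MolFromSmiles(smiles)


def safe_inchi(mol):
    try:
        return Chem.MolToInchi(mol) or ""
    except Exception:
        return ""


def safe_inchikey(mol):
    try:
        return Chem.MolToInchiKey(mol) or ""
    except Exception:
        return ""


def task_parse(args):
    emit(["id", "is_valid", "failure_stage", "canonical_smiles", "inchi",
          "inchikey"])
    for rid, smi, *_ in read_rows():
        mol = mol_from(smi)
        if mol is None:
            emit([rid, 0, "parse", "", "", ""])
            continue
        try:
            can = Chem.MolToSmiles(mol)
        except Exception:
            can = ""
        if not can:
            emit([rid, 0, "canonical_write", "", "", ""])
            continue
        inchi = safe_inchi(mol)
        if not inchi:
            emit([rid, 0, "inchi_write", can, "", ""])
            continue
        ikey = safe_inchikey(mol)
        if not ikey:
            emit([rid, 0, "inchikey_write", can, inchi, ""])
            continue
        emit([rid, 1, "none", can, inchi, ikey])


def task_strip(args):
    emit(["id", "smiles_out"])
    for rid, smi, *_ in read_rows():
        mol = mol_from(smi)
        if mol is None:
            emit([rid, ""])
            continue
        Chem.RemoveStereochemistry(mol)
        emit([rid, Chem.MolToSmiles(mol)])


def task_enumerate(args):
    emit(["id", "variant"])
    for idx, (rid, smi, *_) in enumerate(read_rows()):
        mol = mol_from(smi)
        if mol is None:
            for _ in range(args.k):
                emit([rid, ""])
            continue
        rng = random.Random(args.seed * 1000003 + idx)
        n = mol.GetNumAtoms()
        for _ in range(args.k):
            perm = list(range(n))
            rng.shuffle(perm)
            ren = Chem.RenumberAtoms(mol, perm)
            emit([rid, Chem.MolToSmiles(ren, canonical=False)])


def task_descriptors(args):
    names = PANEL10 if args.panel == "panel10" else PANEL27
    emit(["id"] + names)
    fns = [getattr(Descriptors, n) for n in names]
    for rid, smi, *_ in read_rows():
        mol = mol_from(smi)
        if mol is None:
            emit([rid] + [""] * len(names))
            continue
        emit([rid] + [repr(float(fn(mol))) for fn in fns])


def task_fragments(args):
    emit(["id", "n_heavy", "frags"])
    for rid, smi, *_ in read_rows():
        mol = mol_from(smi)
        if mol is None:
            emit([rid, "", ""])
            continue
        bit_info = {}
        AllChem.GetMorganFingerprint(mol, args.radius, bitInfo=bit_info)
        best = {}
        for bit, occurrences in bit_info.items():
            for atom, rad in occurrences:
                if atom not in best or rad > best[atom][0]:
                    best[atom] = (rad, bit)
        frags = " ".join(str(best[a][1]) for a in sorted(best))
        emit([rid, mol.GetNumHeavyAtoms(), frags])


_normalizer = None
_uncharger = None


def standardize_mol(mol):
    global _normalizer, _uncharger
    if _normalizer is None:
        _normalizer = rdMolStandardize.Normalizer()
        _uncharger = rdMolStandardize.Uncharger()
    mol = _normalizer.normalize(mol)
    mol = _uncharger.uncharge(mol)
    Chem.SanitizeMol(mol)
    return Chem.RemoveHs(mol)


def task_standardize(args):
    emit(["id", "smiles_out"])
    for rid, smi, *_ in read_rows():
        mol = mol_from(smi)
        if mol is None:
            emit([rid, ""])
            continue
        try:
            emit([rid, Chem.MolToSmiles(standardize_mol(mol))])
        except Exception:
            emit([rid, ""])


def load_salts(path):
    salts = set()
    if not path:
        return salts
    with open(path) as fh:
        for line in fh:
            line = line.split("#")[0].strip()
            if not line:
                continue
            smi = line.split()[0]
            mol = mol_from(smi)
            if mol is not None:
                salts.add(Chem.MolToSmiles(mol))
    return salts


def task_parent(args):
    salts = load_salts(args.salts)
    emit(["id", "parent_smiles", "no_parent"])
    for rid, smi, *_ in read_rows():
        mol = mol_from(smi)
        if mol is None:
            emit([rid, "", 1])
            continue
        frags = Chem.GetMolFrags(mol, asMols=True, sanitizeFrags=False)
        kept = [f for f in frags if Chem.MolToSmiles(f) not in salts]
        if not kept:
            emit([rid, "", 1])
            continue
        parent = Chem.RWMol(max(kept, key=lambda f: f.GetNumHeavyAtoms()))
        for atom in parent.GetAtoms():
            if atom.GetIsotope() != 0:
                atom.SetIsotope(0)
                if atom.GetFormalCharge() == 0:
                    # bracket isotope atoms carry fixed H counts; let the
                    # sanitizer restore the implicit-H bookkeeping
                    atom.SetNumExplicitHs(atom.GetTotalNumHs())
                    atom.SetNumRadicalElectrons(0)
                    atom.SetNoImplicit(False)
        try:
            Chem.SanitizeMol(parent)
            parent = Chem.RemoveHs(parent)
        except Exception:
            pass
        emit([rid, Chem.MolToSmiles(parent), 0])


def valence_violation(mol):
    for atom in mol.GetAtoms():
        allowed = VALENCE_TABLE.get(atom.GetSymbol())
        if allowed is None or atom.GetFormalCharge() != 0:
            continue
        if atom.GetTotalValence() > allowed:
            return True
    return False


def task_checkfacts(args):
    emit(["id", "has_unspec_stereo", "uncharge_changes", "has_isotope",
          "n_fragments", "roundtrip_mismatch", "valence_violation",
          "unsupported_element", "identifier_failure"])
    for rid, smi, *_ in read_rows():
        mol = mol_from(smi)
        if mol is None:
            emit([rid] + [""] * 8)
            continue
        stereo = Chem.FindPotentialStereo(mol)
        unspec = int(any(str(e.specified) == "Unspecified" for e in stereo))
        can = Chem.MolToSmiles(mol)
        try:
            unch = standardize_mol(Chem.MolFromSmiles(can))
            uncharge_changes = int(Chem.MolToSmiles(unch) != can)
        except Exception:
            uncharge_changes = 1
        isotope = int(any(a.GetIsotope() != 0 for a in mol.GetAtoms()))
        n_frag = len(Chem.GetMolFrags(mol))
        reparse = Chem.MolFromSmiles(can)
        mismatch = int(reparse is None or Chem.MolToSmiles(reparse) != can)
        bad_valence = int(valence_violation(mol))
        bad_elem = int(any(a.GetSymbol() not in ELEMENT_WHITELIST
                           for a in mol.GetAtoms()))
        idfail = int(not safe_inchi(mol) or not safe_inchikey(mol))
        emit([rid, unspec, uncharge_changes, isotope, n_frag, mismatch,
              bad_valence, bad_elem, idfail])


def corrupt_one(mol, op, rng):
    """Return a corrupted SMILES or None when the op does not apply."""
    if op == "duplicate_rewrite":
        n = mol.GetNumAtoms()
        perm = list(range(n))
        rng.shuffle(perm)
        out = Chem.MolToSmiles(Chem.RenumberAtoms(mol, perm), canonical=False)
        return out if out != Chem.MolToSmiles(mol) else out
    if op == "add_isotope":
        atoms = [a for a in mol.GetAtoms() if a.GetSymbol() != "H"]
        atom = rng.choice(atoms)
        atom.SetIsotope(int(round(atom.GetMass())) + 1)
        return Chem.MolToSmiles(mol)
    if op == "add_charge":
        # deprotonate an O-H if present, else protonate a neutral N
        for atom in mol.GetAtoms():
            if (atom.GetSymbol() == "O" and atom.GetTotalNumHs() == 1
                    and atom.GetFormalCharge() == 0):
                atom.SetFormalCharge(-1)
                atom.SetNumExplicitHs(0)
                atom.SetNoImplicit(True)
                return Chem.MolToSmiles(mol)
        for atom in mol.GetAtoms():
            if (atom.GetSymbol() == "N" and atom.GetFormalCharge() == 0
                    and not atom.GetIsAromatic()
                    and atom.GetTotalValence() < 4):
                atom.SetFormalCharge(1)
                atom.SetNumExplicitHs(atom.GetTotalNumHs() + 1)
                return Chem.MolToSmiles(mol)
        return None
    if op == "add_stereo":
        centres = [e for e in Chem.FindPotentialStereo(mol)
                   if str(e.type) == "Atom_Tetrahedral"
                   and str(e.specified) == "Unspecified"]
        if not centres:
            return None
        idx = int(rng.choice(centres).centeredOn)
        tag = rng.choice([Chem.ChiralType.CHI_TETRAHEDRAL_CW,
                          Chem.ChiralType.CHI_TETRAHEDRAL_CCW])
        mol.GetAtomWithIdx(idx).SetChiralTag(tag)
        out = Chem.MolToSmiles(mol)
        return out if "@" in out else None
    if op == "severe_valence":
        # hypervalent exotic-metal fragment: parses and yields identifiers,
        # but trips the severe (penalty >5) structure-checker rules
        return Chem.MolToSmiles(mol) + ".C[W](C)(C)(C)(C)C"
    raise ValueError("unknown corruption: " + op)


def task_corrupt(args):
    emit(["id", "smiles_out", "ok"])
    for idx, (rid, smi, *rest) in enumerate(read_rows()):
        op = rest[0] if rest else args.op
        mol = mol_from(smi)
        if mol is None:
            emit([rid, "", 0])
            continue
        rng = random.Random(args.seed * 1000003 + idx)
        try:
            out = corrupt_one(Chem.RWMol(mol), op, rng)
        except Exception:
            out = None
        if out is None or mol_from(out) is None:
            emit([rid, "", 0])
        else:
            emit([rid, out, 1])


def main():
    ap = argparse.ArgumentParser()
    ap.add_argument("task", choices=[
        "parse", "strip", "enumerate", "descriptors", "fragments",
        "standardize", "parent", "checkfacts", "corrupt"])
    ap.add_argument("--k", type=int, default=1)
    ap.add_argument("--seed", type=int, default=0)
    ap.add_argument("--radius", type=int, default=2)
    ap.add_argument("--panel", default="panel10")
    ap.add_argument("--salts", default="")
    ap.add_argument("--op", default="")
    args = ap.parse_args()
    globals()["task_" + args.task](args)


if __name__ == "__main__":
    main()
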