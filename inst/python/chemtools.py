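"""RDKit back-end for duotox structure perception.

Invoked by the R package as a subprocess with a JSON request file and a JSON
response file; never imported by users directly. Three actions:

  read      parse SMILES/SDF/MOL2 into molblocks (per-entry failure report)
  prepare   embed/minimize a 3D conformer and compute per-atom weights
  mcs       maximum-common-substructure atom map between two molblocks
"""
import json
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem, rdFMCS, rdMolDescriptors

RDLogger.DisableLog("rdApp.*")

PT = Chem.GetPeriodicTable()

# heavy-atom donor/acceptor perception (donor flag on the donor heavy atom)
DONOR_SMARTS = Chem.MolFromSmarts(
    "[$([N;!H0;v3,v4&+1]),$([O;!H0;+0]),$([S;!H0;+0]),$([n;H1;+0])]")
ACCEPTOR_SMARTS = Chem.MolFromSmarts(
    "[$([O;v2;+0]),$([O;-]),$([S;v2;H0]),$([S;-]),"
    "$([N;v3;!$(N-*=[O,N,P,S])]),$([nH0;+0]),$([o;+0])]")


def _fail(msg, kind="input"):
    return {"error": msg, "kind": kind}


def read_structures(req):
    fmt = req["format"]
    path = req["path"]
    mols, skipped = [], []
    if fmt == "smiles":
        with open(path) as fh:
            lines = [ln.strip() for ln in fh if ln.strip()]
        if not lines:
            return _fail("no entries in SMILES file")
        for i, line in enumerate(lines, 1):
            parts = line.split()
            m = Chem.MolFromSmiles(parts[0])
            if m is None:
                skipped.append({"index": i, "reason": "unparsable SMILES"})
                continue
            name = parts[1] if len(parts) > 1 else "mol%d" % i
            mols.append({"compound_id": name, "smiles": parts[0],
                         "molblock": Chem.MolToMolBlock(m),
                         "n_atoms": m.GetNumAtoms(), "has_3d": False})
    elif fmt == "sdf":
        suppl = Chem.SDMolSupplier(path, removeHs=False)
        n = len(suppl)
        if n == 0:
            return _fail("no entries in SDF file")
        for i in range(n):
            m = suppl[i]
            if m is None:
                skipped.append({"index": i + 1, "reason": "unparsable SDF entry"})
                continue
            name = m.GetProp("_Name") if m.HasProp("_Name") and m.GetProp("_Name") \
                else "mol%d" % (i + 1)
            has_3d = m.GetNumConformers() > 0 and m.GetConformer().Is3D()
            mols.append({"compound_id": name,
                         "smiles": Chem.MolToSmiles(m),
                         "molblock": Chem.MolToMolBlock(m),
                         "n_atoms": m.GetNumAtoms(), "has_3d": bool(has_3d)})
    elif fmt == "mol2":
        m = Chem.MolFromMol2File(path, removeHs=False)
        if m is None:
            return _fail("unparsable MOL2 file")
        name = m.GetProp("_Name") if m.HasProp("_Name") and m.GetProp("_Name") \
            else "mol1"
        mols.append({"compound_id": name, "smiles": Chem.MolToSmiles(m),
                     "molblock": Chem.MolToMolBlock(m),
                     "n_atoms": m.GetNumAtoms(), "has_3d": True})
    else:
        return _fail("unknown format: %s" % fmt, kind="usage")
    if not mols:
        return _fail("zero parsable entries")
    return {"molecules": mols, "skipped": skipped}


def _perceive_atoms(mol):
    """Per-atom weights on a prepared (explicit-H, 3D) molecule."""
    AllChem.ComputeGasteigerCharges(mol)
    crippen = rdMolDescriptors._CalcCrippenContribs(mol)
    donors = {t[0] for t in mol.GetSubstructMatches(DONOR_SMARTS)}
    acceptors = {t[0] for t in mol.GetSubstructMatches(ACCEPTOR_SMARTS)}
    conf = mol.GetConformer()
    atoms = []
    for a in mol.GetAtoms():
        i = a.GetIdx()
        pos = conf.GetAtomPosition(i)
        rvdw = PT.GetRvdw(a.GetAtomicNum())
        atoms.append({
            "element": a.GetSymbol(),
            "x": pos.x, "y": pos.y, "z": pos.z,
            "charge": float(a.GetDoubleProp("_GasteigerCharge")),
            "steric": rvdw ** 3,
            "hydrophobicity": crippen[i][0],
            "hbd": 1 if i in donors else 0,
            "hba": 1 if i in acceptors else 0,
        })
    return atoms


def prepare(req):
    out = {"molecules": [], "failed": []}
    seed = int(req.get("seed", 1))
    n_conf = int(req.get("n_conformers", 10))
    max_iters = int(req.get("max_iterations", 10000))
    for entry in req["molecules"]:
        cid = entry.get("compound_id", "?")
        try:
            if entry.get("molblock"):
                mol = Chem.MolFromMolBlock(entry["molblock"], removeHs=False)
            else:
                mol = Chem.MolFromSmiles(entry["smiles"])
            if mol is None:
                raise ValueError("unparsable structure")
            mol = Chem.AddHs(mol, addCoords=bool(entry.get("has_3d")))
            energy = None
            if not entry.get("has_3d"):
                params = AllChem.ETKDGv3()
                params.randomSeed = seed
                cids = AllChem.EmbedMultipleConfs(mol, numConfs=n_conf,
                                                  params=params)
                if len(cids) == 0:
                    raise ValueError("3D embedding failed")
                res = AllChem.MMFFOptimizeMoleculeConfs(mol, maxIters=max_iters)
                energies = [e for conv, e in res]
                best = min(range(len(energies)), key=energies.__getitem__)
                energy = energies[best]
                keep = Chem.Conformer(mol.GetConformer(cids[best]))
                mol.RemoveAllConformers()
                mol.AddConformer(keep, assignId=True)
            else:
                ff_ok = AllChem.MMFFOptimizeMolecule(mol, maxIters=max_iters)
                props = AllChem.MMFFGetMoleculeProperties(mol)
                if props is not None:
                    ff = AllChem.MMFFGetMoleculeForceField(mol, props)
                    if ff is not None:
                        energy = ff.CalcEnergy()
            out["molecules"].append({
                "compound_id": cid,
                "atoms": _perceive_atoms(mol),
                "formal_charge": Chem.GetFormalCharge(mol),
                "energy": energy,
                "molblock": Chem.MolToMolBlock(mol),
                "seed": seed,
            })
        except Exception as exc:  # per-molecule failure, not fatal for batch
            out["failed"].append({"compound_id": cid, "reason": str(exc)})
    return out


def _heavy_index_map(mol):
    return [a.GetIdx() for a in mol.GetAtoms() if a.GetAtomicNum() > 1]


def mcs(req):
    ma = Chem.MolFromMolBlock(req["molblock_a"], removeHs=False)
    mb = Chem.MolFromMolBlock(req["molblock_b"], removeHs=False)
    if ma is None or mb is None:
        return _fail("unparsable molblock")
    ha, hb = Chem.RemoveHs(ma), Chem.RemoveHs(mb)
    res = rdFMCS.FindMCS(
        [ha, hb], timeout=int(req.get("timeout", 30)),
        ringMatchesRingOnly=True,
        atomCompare=rdFMCS.AtomCompare.CompareElements,
        bondCompare=rdFMCS.BondCompare.CompareOrder)
    if res.canceled or res.numAtoms == 0:
        return _fail("no common substructure found")
    q = Chem.MolFromSmarts(res.smartsString)
    match_a, match_b = ha.GetSubstructMatch(q), hb.GetSubstructMatch(q)
    if not match_a or not match_b:
        return _fail("substructure match failed")
    ia, ib = _heavy_index_map(ma), _heavy_index_map(mb)
    pairs = [[ia[x] + 1, ib[y] + 1] for x, y in zip(match_a, match_b)]  # 1-based
    return {"n_atoms": res.numAtoms, "n_bonds": res.numBonds,
            "smarts": res.smartsString, "pairs": pairs}


def main():
    req_path, resp_path = sys.argv[1], sys.argv[2]
    with open(req_path) as fh:
        req = json.load(fh)
    action = req.get("action")
    try:
        if action == "read":
            resp = read_structures(req)
        elif action == "prepare":
            resp = prepare(req)
        elif action == "mcs":
            resp = mcs(req)
        else:
            resp = _fail("unknown action: %s" % action, kind="usage")
    except Exception as exc:
        resp = _fail(str(exc), kind="internal")
    with open(resp_path, "w") as fh:
        json.dump(resp, fh)


if __name__ == "__main__":
    main()
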