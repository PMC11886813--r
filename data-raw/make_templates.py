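"""Generate inst/extdata residue template tables from the CCD ideal
coordinates bundled with biotite. Run once; outputs are vendored."""
import numpy as np
import biotite.structure as struc
import biotite.structure.info as info

ATOM14 = {
 "ALA": ["N","CA","C","O","CB"],
 "ARG": ["N","CA","C","O","CB","CG","CD","NE","CZ","NH1","NH2"],
 "ASN": ["N","CA","C","O","CB","CG","OD1","ND2"],
 "ASP": ["N","CA","C","O","CB","CG","OD1","OD2"],
 "CYS": ["N","CA","C","O","CB","SG"],
 "GLN": ["N","CA","C","O","CB","CG","CD","OE1","NE2"],
 "GLU": ["N","CA","C","O","CB","CG","CD","OE1","OE2"],
 "GLY": ["N","CA","C","O"],
 "HIS": ["N","CA","C","O","CB","CG","ND1","CD2","CE1","NE2"],
 "ILE": ["N","CA","C","O","CB","CG1","CG2","CD1"],
 "LEU": ["N","CA","C","O","CB","CG","CD1","CD2"],
 "LYS": ["N","CA","C","O","CB","CG","CD","CE","NZ"],
 "MET": ["N","CA","C","O","CB","CG","SD","CE"],
 "PHE": ["N","CA","C","O","CB","CG","CD1","CD2","CE1","CE2","CZ"],
 "PRO": ["N","CA","C","O","CB","CG","CD"],
 "SER": ["N","CA","C","O","CB","OG"],
 "THR": ["N","CA","C","O","CB","OG1","CG2"],
 "TRP": ["N","CA","C","O","CB","CG","CD1","CD2","NE1","CE2","CE3","CZ2","CZ3","CH2"],
 "TYR": ["N","CA","C","O","CB","CG","CD1","CD2","CE1","CE2","CZ","OH"],
 "VAL": ["N","CA","C","O","CB","CG1","CG2"],
}

CHI = {  # (atom quadruple, pi-symmetric flag)
 "ARG": [("N","CA","CB","CG",0),("CA","CB","CG","CD",0),("CB","CG","CD","NE",0),("CG","CD","NE","CZ",0)],
 "ASN": [("N","CA","CB","CG",0),("CA","CB","CG","OD1",0)],
 "ASP": [("N","CA","CB","CG",0),("CA","CB","CG","OD1",1)],
 "CYS": [("N","CA","CB","SG",0)],
 "GLN": [("N","CA","CB","CG",0),("CA","CB","CG","CD",0),("CB","CG","CD","OE1",0)],
 "GLU": [("N","CA","CB","CG",0),("CA","CB","CG","CD",0),("CB","CG","CD","OE1",1)],
 "HIS": [("N","CA","CB","CG",0),("CA","CB","CG","ND1",0)],
 "ILE": [("N","CA","CB","CG1",0),("CA","CB","CG1","CD1",0)],
 "LEU": [("N","CA","CB","CG",0),("CA","CB","CG","CD1",0)],
 "LYS": [("N","CA","CB","CG",0),("CA","CB","CG","CD",0),("CB","CG","CD","CE",0),("CG","CD","CE","NZ",0)],
 "MET": [("N","CA","CB","CG",0),("CA","CB","CG","SD",0),("CB","CG","SD","CE",0)],
 "PHE": [("N","CA","CB","CG",0),("CA","CB","CG","CD1",1)],
 "PRO": [("N","CA","CB","CG",0),("CA","CB","CG","CD",0)],
 "SER": [("N","CA","CB","OG",0)],
 "THR": [("N","CA","CB","OG1",0)],
 "TRP": [("N","CA","CB","CG",0),("CA","CB","CG","CD1",0)],
 "TYR": [("N","CA","CB","CG",0),("CA","CB","CG","CD1",1)],
 "VAL": [("N","CA","CB","CG1",0)],
}

with open("inst/extdata/residue_atoms.tsv","w") as fa, \
     open("inst/extdata/residue_chi.tsv","w") as fc, \
     open("inst/extdata/residue_bonds.tsv","w") as fb:
    fa.write("aa\tslot\tatom\telement\tx\ty\tz\n")
    fc.write("aa\tchi\ta1\ta2\ta3\ta4\tsymmetric\n")
    fb.write("aa\tatom1\tatom2\n")
    for aa, names in sorted(ATOM14.items()):
        res = info.residue(aa)
        res = res[~np.isin(res.atom_name, ["OXT"]) & (res.element != "H")]
        nm = list(res.atom_name)
        assert set(names) <= set(nm), (aa, names, nm)
        for k, an in enumerate(names):
            i = nm.index(an)
            x, y, z = res.coord[i]
            fa.write(f"{aa}\t{k+1}\t{an}\t{res.element[i]}\t{x:.4f}\t{y:.4f}\t{z:.4f}\n")
        bonds = res.bonds.as_array()
        for a1, a2, _ in bonds:
            n1, n2 = nm[a1], nm[a2]
            if n1 in names and n2 in names:
                fb.write(f"{aa}\t{n1}\t{n2}\n")
        for k, (a1,a2,a3,a4,s) in enumerate(CHI.get(aa, [])):
            fc.write(f"{aa}\t{k+1}\t{a1}\t{a2}\t{a3}\t{a4}\t{s}\n")
print("done")
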