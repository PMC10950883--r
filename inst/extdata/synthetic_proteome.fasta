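>SYNP0001
QPEAHYSLDGNSSVSLRSRKSKCIGIMPETVLAIDPVPDVPGKHNVLLILSTGNAILKYD
PQDAMSIQVKTCDTDTGDHKTENETCDLFLTVCTLQRCDDFGDETDGLIVKRAIFKMNEV
RRALPQTHPLRTIFRLKIMSILIVGAKPEVA
>SYNP0002
TVSCEVVFAKKLWKPMATLSEYRVVDKIFMKIALRYPLQAAHWALSGVDADDSLKNAVTY
NDAVGDSKPVSLRSLPYLQFDPGSAQKARTEYGSLPIVDARLPHLVCMNILPYFIKQTVA
KTVIVLAGQFRMLGRGNASVQNGVIGYKKEMVGLKTVELLIKDQSGAYGAVYGQKPTPHM
PRPHPVTAVRAEMLNWGLIFSLLVGCTFSDSALGLVRNCDHKAQRIIDPLEELFRTTLYA
WRASQSEPRR
>SYNP0003
AVLREEGDSVNVRLVTCQRIPSTLDSHTVGLFGRGWSIGGFENWNLEEVTLCENVAFIEK
KARKSNCNLPEIPTVQSDLPSSGPLRQGDGGGLKLITRPIMVFVMSWQPPDMDADIEGCA
SPGARKDCWALDVRATEKYDIQTGAQGPYDEVCFLEKDLKEFYNQCAVNLA
>SYNP0004
DIIRLYLPVYYKEEVMDVGYNAAGTFALEPLNLYTHMAVPRIGDAGILWDKVVIQVGIKY
GFLKTHDFTWCYEPEDERHRVATGSTLVAVNFTLVAEILHDVIEKQPTEGGHIKYMNNLG
VRSLNSIIAFLHAAKGF
>SYNP0005
FLIPVIGKAHTKDSAGWQIILCNVALVQHAVQWRIAFLEKNLYFRSLQNRDLIHRAIKTS
VKGTMNATVTSVAAEGAGIYAPKSSVGAEEKEIKVDYKGVHIREVWIRFLVRSHAQKGPK
KDEMAEEGVGISVTITTVGANDPVRNTFSLGDPCHRAEEMTAFSESPIIAINFYSRTTMD
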