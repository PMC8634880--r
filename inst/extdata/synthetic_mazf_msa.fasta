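>MazF_synthetic_Da synthetic aligned fixture
TQNRTGDVWCQRFKPTAGCEDRGARPYCMMRWLSTNRLTRGLHTEFISFVITIPYDQKSW------AHYIRHICPMIRGATDGGKSCHVPRFLECHCHAPCKWFSALIRRVRALGVNTFCDAKI
>MazF_synthetic_A synthetic aligned fixture
LQNRTGCVFCQFNKPTEGNEDRGARPYDMMRYLVRNMFTRGLHTCFISFVITIPYDRKSW------AGFIRWIEPMIRGQTDGGKSCPVSRKMYCHCHNPTKWSSASLRLVSTLGVNSFCNAAF
>MazF_synthetic_B synthetic aligned fixture
TQNRTGRVWQQRFKPMCGCEDRLMRPYCGPRWLETNRLTWYLHIHTFSFVWTQPGDSKSWHLHQLSAHYIRHRCPYDKGATDMVKSCCVNRVLQIHCLAPGKKLSALIRFVRAQGVNTHCDAKY
>MazF_synthetic_C synthetic aligned fixture
TQNRTGGSWCQAFKPNFGPEDRGNRPYCVMRGLSTNRLTCGLMTEGISAVGTIPYQQKSWWDYTAYAHYIWHITPMIRGATDGWKSCETDRFLGFDNMAPFKSSSSLIRYNRALWVHTKCDQVI
>MazF_synthetic_D synthetic aligned fixture
PYNRTGDVWCWRFKPTAGCEMDQARPYVMMMWNSENRYTDHFPTEFIKHEMPICYDDKSWSEGWLSEHYIRMICPMIRGLTDGGKSCHFPRVDLCHCKAPCKNFAALILRVRALGHNTCCDAKI
>MazF_synthetic_E synthetic aligned fixture
HQNRWGDHWCCRFEPTKGCEDRGPRPYCMMRWCCTNRLTRGHHTCFGYVVQRIPYDQKSWEQPDSNWNYLRRIDPMYHGATDMGKSCAIPRFLEKHVHAPCQWCSAAIRMVRALRVNTTIDIVA
>MazF_synthetic_F synthetic aligned fixture
TQNTTGDVWCQFFKPTFGCEDAGARPYRMMRWLQTNGLFRRLHTEFTSNPAQIPADTKSWQGSMMGAHYAEFHTVQIRGAGDGGTSVHVPRNLYCHCHAPCKWVSALIRVYRALEIYTFCDMPI
>MazF_synthetic_G synthetic aligned fixture
TQNQTGDVWCQLFKPTAGNEDPGARPYCMMRWLSTNSLTRGLHTWMNSHVNTILYKQKSWSFGATNWHYIRHTHAMSFGTQPKGKFCCVPRSLNCRCGAMQKFFQALIRRVDALGVNLFFDADI
>MazF_synthetic_H synthetic aligned fixture
PQRRTGPVWCQRYKPTLGCEDRGARPCCTMRKLSTNRLFRGTLTEWKSFVITITPQEKPLETLWTDAHYNRYGCPMTQGATTGHKSCHIPRFLECYDHAPCKWQSDLIIRVRAEGFHTMCDVMI
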