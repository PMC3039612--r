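motif	consensus
1	PKYFKHNNFSSFVRQLNTYGFRKIDPDRWEFANECFLRGQKHLLKNIHRRKP
2	NVLMQEVVKLRQQQQTTKWQMQAMEQRLQHMEQRQQQMMSFLAKVMQNP
3	PFLTKTYDMVDDPATDHVISWNEDN
4	SFVRQLNTYGFRKVDPDRWEFANECFLRGQKHLLCNIHRRK
5	SFVVWNPHEFARDLL
6	AGSCPAYADLMEENERLRRENARLTRELAHMKKLCNNIIYFMSNYVDPQQPDAAKAM
7	SGPAPFLTKTYQMVCDPATDHVISWGPCG
8	YFGYEEEIERLKRDK
9	AEINDDFWEQFLTEGPGCCE
10	EMRKELIDAISKKRRRPIDDC
11	SFVVWDPHAFSQTLL
12	YFKHNNFS
13	DNMDVLTEQMGYLSS
14	FLNQLVQQQRRSNWWNDDGNRKRRFQALEHGPVDDQETSGGGAQIIQYCPPVPETSNQPIPANEAFCSTPAQPVSSPALEMPMDV
15	DEDKCVKLFGVSIGDKRMRDH
16	QPWPIYRPRPVYHPIRPCNG
17	PQYQQQSVGSCVEVG
18	GGGGGGGG
19	AAAAAA
20	PMEGLHEVGPP
21	ASLDGQIVKYQPMINEAAK
22	TSFYDDHSSTSKQEMGNLLNQHFSDKLKLGLCPAMTESNIITLSTQSSHEDNGSPHGKHPDCDMMGMECLPLVPQMMELSDTGTSICPSKSVCFTPPINDDGFLPCHLNLTLASCPMDVDKSQIPDANGNTID
23	RCEEAAASERPIKMIRIGEPWIGVPSSGP
24	YDHPWLEQDCQMEAQQNCKNPQYADVIT
25	ELENLALNIQGLGKGKID
26	PEADDMGTGSSLEQGSPVLFEPQDPVEFLIDGIPSDLESSAVDAHGLIAPQDI
27	MDADDDERIWGVDASAALQSSCSGTSQQAYGSHVSDPYLMDIANKPEKFWELDFQALDDGDLQLDKCVIDDPALQQQ
28	MASNNVGTFDSTGNDFTDTSALCEWDDMDIFGGELEHILQQPEQDFQVDP
29	SPTYSGEEQVISSNS
30	AMLRKILKLDSSHRFESMGNSDN
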