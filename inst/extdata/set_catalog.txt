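# SET-domain architecture rule catalog.
#
# Grammar (whitespace-separated tokens, '#' starts a comment line):
#   species <16 species codes>          -- declares the presence-column order
#   <id> <backbone> extras=<list|-> presence=<16 of +/-> [orphan] [ambig]
#
# <id>       hierarchical label, e.g. II-2A = class II, subclass 2, subdivision A;
#            ids ending in "-Orphan" are per-family orphan rows, V-* are class V.
# <backbone> hyphen-joined canonical domain names, N->C signature architecture.
# extras     comma-separated domain names that may co-occur without changing
#            the label ('-' = none recorded).
# presence   phyletic +/- string in the declared species column order.
# orphan     row is matched by SET-domain homology, never by exact architecture
#            (exempt from backbone uniqueness).
# ambig      backbone is a declared duplicate of an earlier row; exact matches
#            resolve to the earlier row unless homology says otherwise.
#
species At Os Pa Sm Pp Mp Nm Kf Mr Mpu Ot Ol Cv Cr Vc Cp

# -- Class I, E(z): seven architecture variants -------------------------------
I-1 SANT-TCR-PreSET-SET     extras=-        presence=-+--------------
I-2 TCR-PreSET-SET          extras=-        presence=---+------------
I-3 TCR-Vn-SET              extras=-        presence=----++----------
I-4 TCR-SET                 extras=-        presence=+-+---+++---++--
I-5 CSR-SET                 extras=-        presence=----------++----
I-6 MSL-SET                 extras=-        presence=----------++----
I-7 ALDH_SF-TCR-SET         extras=-        presence=---------+------

# -- Class II, Ash ------------------------------------------------------------
II-1A AWS-SET               extras=TUDOR,PLN03081                  presence=++++-++-+-++---+
II-1B AWS-SET-PostSET       extras=-                               presence=-------+----+---
II-2A PHD-PHD-PHD-AWS-SET   extras=-                               presence=----+++---------
II-2B PHD-AWS-SET           extras=-                               presence=+---------------
II-3A ZnF_C2H2-AWS-SET-PostSET extras=ATP11,PHA03420,CITED,FAM196,SRI presence=++-+++-+--------
II-3B ZnF_C2H2-AWS-SET      extras=PHA,SOX,Drf_FM1,Me425_SD1       presence=----++----------
II-3C ZnF_C2H2-AWS-SET-ZnF_C2H2-ZnF_C2H2 extras=-                  presence=--------+-------
II-Orphan SET               extras=LIM                             presence=+---++-+-++-++++ orphan

# -- Class III, Trx -----------------------------------------------------------
III-1A PWWP-FYR-PHD-PHD-SET extras=TUDOR                           presence=+--++++------+--
III-1B PWWP-FYR-PHD-SET     extras=-                               presence=---+--------+---
III-1C FYR-PHD-PHD-SET      extras=-                               presence=------+-------+-
III-1D ZnF_C2H2-PHD-PHD-PHD-PHD-PHD-FYR-SET-PostSET extras=-       presence=-------+--------
III-1E PWWP-FYR-PHD-PHD-SET-PostSET extras=TUDOR,UDS               presence=-+--------------
III-2A PWWP-PHD-PHD-PHD-SET extras=COG5141                         presence=++++-+----------
III-2B PWWP-PHD-PHD-PHD-SET-PostSET extras=-                       presence=----+--+--------
III-2C PWWP-PHD-HMGb-SAND-PHD-PHD-ZnF_C2H2-SET-PostSET extras=NHPGB presence=--------+-++----
III-2D PWWP-AWS-SET         extras=TUDOR                           presence=-------------+--
III-3A PHD-PHD-SET          extras=Agnet                           presence=-+-++--+-+-+----
III-3B PHD-PHD-SET-PostSET  extras=DUF3839,Jas                     presence=----++-------++-
III-3C PHD-SET              extras=BAH                             presence=+++-+-+--+------
III-3D PHD-PreSET-SET       extras=-                               presence=-----+----------
III-3E PHD-SET-PostSET      extras=-                               presence=------+---------
III-3F PHD-HMG-SET          extras=-                               presence=---------+------
III-4A ZnF_C2H2-GYF-HMGCOA-SET-PostSET extras=PTZ,GY,MM_COA        presence=---+------------
III-4B SET-PostSET          extras=TUDOR                           presence=-++--+++----++-+
III-Orphan SET              extras=-                               presence=++-------------- orphan

# -- Class IV, Su(var)3-9 -----------------------------------------------------
IV-1A SRA-PreSET-SET        extras=DUF3574,Treacle,PPR,Pinin_SDK,COG3440 presence=+++++-++-+--+++-
IV-1B SRA-SET               extras=-                               presence=---------+--+---
IV-1C SRA-PreSET-SET-SET    extras=-                               presence=-------------+--
IV-2A PreSET-SET            extras=LaMG,COG5281                    presence=++++++++-+------
IV-2B PHD-PreSET-SET        extras=TPR                             presence=---+------------ ambig
IV-2C ZnF_C2H2-ZnF_C2H2-PreSET-SET-PostSET extras=-                presence=-----+----------
IV-2D WIYLD-PreSET-SET      extras=DUF5102,CNDH2_M                 presence=+++--+----------
IV-2E PreSET-SET-PostSET    extras=-                               presence=-+----+---------
IV-2F ZnF-PreSET-SET        extras=-                               presence=-++-------------
IV-2G PreSET-AWS-SET        extras=-                               presence=+---------------
IV-Orphan SET               extras=-                               presence=----++-+-+++++++ orphan

# -- Class V: Orphan / SETD / TPR (rule rows; phyletic data not tabulated) ----
V-SETD SET-Rubis_subs_bind  extras=-                               presence=----------------
V-TPR  TPR                  extras=-                               presence=----------------
V-Orphan SET                extras=RCC1,bHLH_MYC,HLH,BASP1,rp1A,DUF4239 presence=---------------- orphan
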