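HETATM    1  C1  NAG G   1       0.000  -1.500   0.000  1.00  0.00      GLYC C  
HETATM    2  C2  NAG G   1       0.000  -0.750  -1.299  1.00  0.00      GLYC C  
HETATM    3  C3  NAG G   1       0.000   0.750  -1.299  1.00  0.00      GLYC C  
HETATM    4  C4  NAG G   1       0.000   1.500  -0.000  1.00  0.00      GLYC C  
HETATM    5  C5  NAG G   1       0.000   0.750   1.299  1.00  0.00      GLYC C  
HETATM    6  O5  NAG G   1       0.000  -0.750   1.299  1.00  0.00      GLYC O  
HETATM    7  C1  NAG G   2       5.500  -1.500   0.000  1.00  0.00      GLYC C  
HETATM    8  C2  NAG G   2       5.500  -0.750  -1.299  1.00  0.00      GLYC C  
HETATM    9  C3  NAG G   2       5.500   0.750  -1.299  1.00  0.00      GLYC C  
HETATM   10  C4  NAG G   2       5.500   1.500  -0.000  1.00  0.00      GLYC C  
HETATM   11  C5  NAG G   2       5.500   0.750   1.299  1.00  0.00      GLYC C  
HETATM   12  O5  NAG G   2       5.500  -0.750   1.299  1.00  0.00      GLYC O  
HETATM   13  C1  BMA G   3      11.000  -1.500   0.000  1.00  0.00      GLYC C  
HETATM   14  C2  BMA G   3      11.000  -0.750  -1.299  1.00  0.00      GLYC C  
HETATM   15  C3  BMA G   3      11.000   0.750  -1.299  1.00  0.00      GLYC C  
HETATM   16  C4  BMA G   3      11.000   1.500  -0.000  1.00  0.00      GLYC C  
HETATM   17  C5  BMA G   3      11.000   0.750   1.299  1.00  0.00      GLYC C  
HETATM   18  O5  BMA G   3      11.000  -0.750   1.299  1.00  0.00      GLYC O  
HETATM   19  C1  MAN G   4      16.497   2.879   0.000  1.00  0.00      GLYC C  
HETATM   20  C2  MAN G   4      15.998   3.439  -1.299  1.00  0.00      GLYC C  
HETATM   21  C3  MAN G   4      15.002   4.561  -1.299  1.00  0.00      GLYC C  
HETATM   22  C4  MAN G   4      14.503   5.121  -0.000  1.00  0.00      GLYC C  
HETATM   23  C5  MAN G   4      15.002   4.561   1.299  1.00  0.00      GLYC C  
HETATM   24  O5  MAN G   4      15.998   3.439   1.299  1.00  0.00      GLYC O  
HETATM   25  C1  NAG G   5      19.540   8.092  -1.299  1.00  0.00      GLYC C  
HETATM   26  C2  NAG G   5      20.921   6.316   0.000  1.00  0.00      GLYC C  
HETATM   27  C3  NAG G   5      20.460   6.908  -1.299  1.00  0.00      GLYC C  
HETATM   28  C4  NAG G   5      19.079   8.684  -0.000  1.00  0.00      GLYC C  
HETATM   29  C5  NAG G   5      19.540   8.092   1.299  1.00  0.00      GLYC C  
HETATM   30  O5  NAG G   5      20.460   6.908   1.299  1.00  0.00      GLYC O  
HETATM   31  C1  GAL G   6      25.421   9.816   0.000  1.00  0.00      GLYC C  
HETATM   32  C2  GAL G   6      24.960  10.408  -1.299  1.00  0.00      GLYC C  
HETATM   33  C3  GAL G   6      24.040  11.592  -1.299  1.00  0.00      GLYC C  
HETATM   34  C4  GAL G   6      23.579  12.184  -0.000  1.00  0.00      GLYC C  
HETATM   35  C5  GAL G   6      24.040  11.592   1.299  1.00  0.00      GLYC C  
HETATM   36  O5  GAL G   6      24.960  10.408   1.299  1.00  0.00      GLYC O  
HETATM   37  C1  SIA G   7      28.540  15.092  -1.299  1.00  0.00      GLYC C  
HETATM   38  C2  SIA G   7      29.921  13.316   0.000  1.00  0.00      GLYC C  
HETATM   39  C3  SIA G   7      29.460  13.908  -1.299  1.00  0.00      GLYC C  
HETATM   40  C4  SIA G   7      28.079  15.684  -0.000  1.00  0.00      GLYC C  
HETATM   41  C5  SIA G   7      28.540  15.092   1.299  1.00  0.00      GLYC C  
HETATM   42  O5  SIA G   7      29.460  13.908   1.299  1.00  0.00      GLYC O  
HETATM   43  C1  MAN G   8      14.503  -5.121   0.000  1.00  0.00      GLYC C  
HETATM   44  C2  MAN G   8      15.002  -4.561  -1.299  1.00  0.00      GLYC C  
HETATM   45  C3  MAN G   8      15.998  -3.439  -1.299  1.00  0.00      GLYC C  
HETATM   46  C4  MAN G   8      16.497  -2.879  -0.000  1.00  0.00      GLYC C  
HETATM   47  C5  MAN G   8      15.998  -3.439   1.299  1.00  0.00      GLYC C  
HETATM   48  O5  MAN G   8      15.002  -4.561   1.299  1.00  0.00      GLYC O  
HETATM   49  C1  NAG G   9      20.460  -6.908   1.299  1.00  0.00      GLYC C  
HETATM   50  C2  NAG G   9      19.079  -8.684   0.000  1.00  0.00      GLYC C  
HETATM   51  C3  NAG G   9      19.540  -8.092  -1.299  1.00  0.00      GLYC C  
HETATM   52  C4  NAG G   9      20.460  -6.908  -1.299  1.00  0.00      GLYC C  
HETATM   53  C5  NAG G   9      20.921  -6.316  -0.000  1.00  0.00      GLYC C  
HETATM   54  O5  NAG G   9      19.540  -8.092   1.299  1.00  0.00      GLYC O  
HETATM   55  C1  GAL G  10      23.579 -12.184   0.000  1.00  0.00      GLYC C  
HETATM   56  C2  GAL G  10      24.040 -11.592  -1.299  1.00  0.00      GLYC C  
HETATM   57  C3  GAL G  10      24.960 -10.408  -1.299  1.00  0.00      GLYC C  
HETATM   58  C4  GAL G  10      25.421  -9.816  -0.000  1.00  0.00      GLYC C  
HETATM   59  C5  GAL G  10      24.960 -10.408   1.299  1.00  0.00      GLYC C  
HETATM   60  O5  GAL G  10      24.040 -11.592   1.299  1.00  0.00      GLYC O  
HETATM   61  C1  SIA G  11      28.079 -15.684   0.000  1.00  0.00      GLYC C  
HETATM   62  C2  SIA G  11      28.540 -15.092  -1.299  1.00  0.00      GLYC C  
HETATM   63  C3  SIA G  11      29.460 -13.908  -1.299  1.00  0.00      GLYC C  
HETATM   64  C4  SIA G  11      29.921 -13.316  -0.000  1.00  0.00      GLYC C  
HETATM   65  C5  SIA G  11      29.460 -13.908   1.299  1.00  0.00      GLYC C  
HETATM   66  O5  SIA G  11      28.540 -15.092   1.299  1.00  0.00      GLYC O  
CONECT    1    2
CONECT    2    3
CONECT    3    4
CONECT    4    5
CONECT    5    6
CONECT    6    1
CONECT    7    8
CONECT    8    9
CONECT    9   10
CONECT   10   11
CONECT   11   12
CONECT   12    7
CONECT    4    7
CONECT   13   14
CONECT   14   15
CONECT   15   16
CONECT   16   17
CONECT   17   18
CONECT   18   13
CONECT   10   13
CONECT   19   20
CONECT   20   21
CONECT   21   22
CONECT   22   23
CONECT   23   24
CONECT   24   19
CONECT   16   19
CONECT   25   26
CONECT   26   27
CONECT   27   28
CONECT   28   29
CONECT   29   30
CONECT   30   25
CONECT   22   25
CONECT   31   32
CONECT   32   33
CONECT   33   34
CONECT   34   35
CONECT   35   36
CONECT   36   31
CONECT   28   31
CONECT   37   38
CONECT   38   39
CONECT   39   40
CONECT   40   41
CONECT   41   42
CONECT   42   37
CONECT   34   37
CONECT   43   44
CONECT   44   45
CONECT   45   46
CONECT   46   47
CONECT   47   48
CONECT   48   43
CONECT   16   43
CONECT   49   50
CONECT   50   51
CONECT   51   52
CONECT   52   53
CONECT   53   54
CONECT   54   49
CONECT   46   49
CONECT   55   56
CONECT   56   57
CONECT   57   58
CONECT   58   59
CONECT   59   60
CONECT   60   55
CONECT   52   55
CONECT   61   62
CONECT   62   63
CONECT   63   64
CONECT   64   65
CONECT   65   66
CONECT   66   61
CONECT   58   61
END
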